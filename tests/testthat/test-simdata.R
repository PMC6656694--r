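test_that("simulation is bitwise reproducible given the seed", {
  tmpl <- fxPbmcTemplates()
  cfg <- simConfig(2000, seed = 99, templates = tmpl, beadFraction = 0.05,
                   doubletRate = 0.02, deadFraction = 0.03)
  a <- simulateSample(cfg)
  b <- simulateSample(cfg)
  expect_identical(exprs(a$matrix), exprs(b$matrix))
  expect_identical(a$truth, b$truth)
})

test_that("degenerate configurations behave as documented", {
  tmpl <- fxPbmcTemplates()
  one <- tmpl[1]
  one[[1]]$frequency <- 1
  cfg <- simConfig(500, seed = 3, templates = one)
  sim <- simulateSample(cfg)
  expect_true(all(sim$truth$label == one[[1]]$name))
  expect_false(any(sim$truth$bead | sim$truth$doublet | sim$truth$dead))

  # invalid configurations fail before any event is produced
  expect_error(simConfig(0, 1, tmpl), "nEvents")
  expect_error(simConfig(100, 1, tmpl, beadFraction = 1.5), "\\[0, 1\\]")
  bad <- tmpl
  bad[[1]]$frequency <- bad[[1]]$frequency + 0.1
  expect_error(simConfig(100, 1, bad), "sum to 1")
  expect_error(simConfig(100, 1, tmpl, drift = function(t) 0 * t), "positive")
})

test_that("realized composition follows the template frequencies", {
  sim <- fxPbmcSim()
  live <- !(sim$truth$bead | sim$truth$doublet | sim$truth$dead)
  tab <- table(sim$truth$label[live]) / sum(live)
  for (nm in names(sim$trueFreq)) {
    p <- sim$trueFreq[[nm]]
    expect_lt(abs(tab[[nm]] - p), tol4se(p, sum(live)))
  }
})

test_that("drift multiplies raw mass-channel intensities", {
  tmpl <- fxPbmcTemplates()
  base <- simulateSample(simConfig(1000, seed = 5, templates = tmpl))
  drifted <- simulateSample(simConfig(1000, seed = 5, templates = tmpl,
                                      drift = function(t) rep(1, length(t))))
  # unit drift leaves the matrix unchanged
  expect_identical(exprs(base$matrix), exprs(drifted$matrix))
  halved <- simulateSample(simConfig(1000, seed = 5, templates = tmpl,
                                     drift = function(t) rep(0.5, length(t))))
  meta <- channelMeta(base$matrix)
  mass <- meta$name[!meta$class %in% c("time", "length")]
  expect_equal(exprs(halved$matrix)[, mass], exprs(base$matrix)[, mass] / 2)
})

test_that("replicate pairs share their true composition", {
  tmpl <- fxPbmcTemplates()
  cfg <- simConfig(3000, seed = 21, templates = tmpl)
  pair <- simulateReplicatePair(cfg, technicalNoiseSd = 0.05)
  expect_identical(pair$a$trueFreq, pair$b$trueFreq)
  expect_error(simulateReplicatePair(cfg, technicalNoiseSd = -1), ">= 0")
  # zero technical noise: the two draws come from identical distributions;
  # their channel means agree to sampling error
  pair0 <- simulateReplicatePair(simConfig(5000, seed = 22, templates = tmpl),
                                 technicalNoiseSd = 0)
  ma <- colMeans(asinh(exprs(pair0$a$matrix) / 5))
  mb <- colMeans(asinh(exprs(pair0$b$matrix) / 5))
  keep <- channelMeta(pair0$a$matrix)$class == "antibody"
  expect_lt(max(abs(ma[keep] - mb[keep])), 0.1)
})

test_that("the bmt cohort reproduces the published cohort shape", {
  co <- simulateCohort(nSamples = 28, seed = 17, eventData = FALSE)
  md <- co$metadata
  expect_identical(nrow(md), 28L)
  expect_identical(length(unique(md$donor)), 15L)
  expect_identical(sum(md$group == "GvHD"), 6L)
  expect_identical(length(unique(md$donor[md$group == "GvHD"])), 3L)
  # the GvHD group median parameter for CD27- B cells is 0.44%, the
  # non-GvHD parameter 3.33%; naive CD4: 0.09% vs 0.3%
  eff <- gvhdEffectTable()
  expect_identical(eff$median_pct[eff$population == "CD27- B cells"], 0.44)
  expect_identical(eff$median_pct[eff$population == "CD4 T naive"], 0.09)
  expect_error(simulateCohort(profile = "pbmc"), "unknown cohort profile")
  expect_error(simulateCohort(
    effectTable = data.frame(population = "Gremlins", group = "GvHD",
                             median_pct = 1), eventData = FALSE),
    "unknown population")
})

test_that("cohort frequencies scatter around the group medians", {
  co <- simulateCohort(nSamples = 28, seed = 400, eventData = FALSE)
  g <- co$metadata$group == "GvHD"
  # log-scale location of the draws matches the generator parameter
  # (logit-normal perturbations preserve the median)
  m <- median(co$trueFreq["CD27- B cells", !g])
  expect_lt(abs(log(m / 0.0333)), 2 * 0.7 / sqrt(22) * 4)
  expect_true(all(abs(colSums(co$trueFreq) - 1) < 1e-9))
})

test_that("barcoded pools carry k-of-n patterns and reject bad schemes", {
  tmpl <- fxPbmcTemplates()
  cfgs <- list(simConfig(800, 1, tmpl), simConfig(800, 2, tmpl))
  sch <- list(s1 = c("102Pd", "104Pd", "105Pd"),
              s2 = c("106Pd", "108Pd", "110Pd"))
  pool <- simulateBarcodedPool(cfgs, sch, seed = 9)
  expect_setequal(unique(pool$truth$sample), c("s1", "s2"))
  meta <- channelMeta(pool$matrix)
  expect_identical(sum(meta$class == "barcode"), 6L)
  # each event's top-3 barcode channels match its sample's code
  y <- asinh(exprs(pool$matrix)[, meta$name[meta$class == "barcode"]] / 5)
  top <- t(apply(y, 1, function(r) sort(order(r, decreasing = TRUE)[1:3])))
  codeIdx <- lapply(sch, function(code)
    sort(match(code, meta$metal[meta$class == "barcode"])))
  ok <- vapply(seq_len(nrow(top)), function(i)
    identical(as.integer(top[i, ]), as.integer(codeIdx[[pool$truth$sample[i]]])),
    logical(1))
  expect_gt(mean(ok), 0.99)

  expect_error(simulateBarcodedPool(cfgs, list(s1 = sch$s1, s2 = sch$s1)),
               "duplicate")
  # two distinct codes of equal k always differ by Hamming >= 2; mixed
  # code lengths are rejected outright
  expect_error(simulateBarcodedPool(
    cfgs, list(s1 = c("102Pd", "104Pd", "105Pd"),
               s2 = c("102Pd", "104Pd"))), "same number")
  # a 3-of-6 scheme supports choose(6, 3) = 20 distinct codes, and all
  # pairs of distinct k-of-k' codes differ by Hamming distance >= 2
  codes <- combn(c("102Pd", "104Pd", "105Pd", "106Pd", "108Pd", "110Pd"), 3,
                 simplify = FALSE)
  expect_length(codes, 20)
})
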