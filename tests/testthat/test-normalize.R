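test_that("bead identification follows the all-channel rule", {
  sim <- fxPbmcSim()
  mask <- identifyBeads(sim$matrix)
  expect_lt(abs(mean(mask) - 0.05), tol4se(0.05, nEvents(sim$matrix)))
  # agreement with ground truth
  expect_gt(mean(mask == sim$truth$bead), 0.999)

  # an event high in only 3 of the bead channels is not a bead
  panel <- fxPanel()
  meta <- CytoMonitor:::.panelChannelMeta(panel)
  beadChans <- meta$name[!is.na(meta$metal) &
                         meta$metal %in% CytoMonitor:::.EQ_BEAD_METALS]
  x <- matrix(1, 2, nrow(meta), dimnames = list(NULL, meta$name))
  x[, beadChans] <- 5 * sinh(5.5)          # event 1: all five high
  x[2, beadChans[1]] <- 5 * sinh(0.2)      # event 2: one channel low
  m <- new("EventMatrix", exprs = x, channelMeta = meta,
           time = c(0, 1), scale = "raw", scaleFactors = numeric(0))
  mask <- identifyBeads(m)
  expect_identical(mask, c(TRUE, FALSE))

  # no beads expected: empty mask and identity factors with a warning
  clean <- simulateSample(simConfig(1500, seed = 31,
                                    templates = fxPbmcTemplates()))
  mask0 <- identifyBeads(clean$matrix)
  expect_identical(sum(mask0), 0L)
  expect_warning(model <- fitBeadModel(clean$matrix, mask0), "identity")
  expect_true(all(model$factors == 1))
})

test_that("normalization is the identity for drift-free data", {
  tmpl <- fxPbmcTemplates()
  sim <- simulateSample(simConfig(20000, seed = 33, templates = tmpl,
                                  beadFraction = 0.1))
  nr <- beadNormalize(sim$matrix)
  expect_identical(dim(nr$matrix), dim(sim$matrix))
  # constant bead intensities over time: factors within bead noise of 1
  expect_lt(max(abs(nr$model$factors - 1)), 0.02)
})

test_that("a constructed drift is inverted to within 2%", {
  tmpl <- fxPbmcTemplates()
  drift <- function(t) 1 - 0.4 * t / 600    # sensitivity decays to 60%
  sim <- simulateSample(simConfig(30000, seed = 34, templates = tmpl,
                                  beadFraction = 0.1, drift = drift))
  mask <- identifyBeads(sim$matrix)
  nr <- beadNormalize(sim$matrix, beadMask = mask)
  # correction factor times true drift is constant over the interpolated
  # span (outside the first/last window centers the factor is held flat)
  tm <- acqTime(sim$matrix)
  span <- range(nr$model$windows$time)
  interior <- tm >= span[1] & tm <= span[2]
  resid <- nr$model$factors[interior] * drift(tm[interior])
  expect_lt(max(abs(resid / mean(resid) - 1)), 0.02)
  # post-normalization bead medians are flat across windows
  refit <- fitBeadModel(nr$matrix, mask)
  expect_lt(max(abs(refit$windows$factor - 1)), 0.02)
  # a second application is the identity to within 2%
  nr2 <- beadNormalize(nr$matrix, beadMask = mask)
  expect_lt(max(abs(nr2$model$factors - 1)), 0.02)
  # the factor profile mirrors the inverse drift across the span
  f <- nr$model$factors
  ratio <- median(f[tm > span[2] - 50 & tm <= span[2]]) /
    median(f[tm >= span[1] & tm < span[1] + 50])
  expected <- drift(span[1] + 25) / drift(span[2] - 25)
  expect_lt(abs(ratio / expected - 1), 0.03)
})

test_that("time-locality: early beads do not move late factors", {
  tmpl <- fxPbmcTemplates()
  sim <- simulateSample(simConfig(20000, seed = 35, templates = tmpl,
                                  beadFraction = 0.1))
  mask <- identifyBeads(sim$matrix)
  m <- sim$matrix
  model <- fitBeadModel(m, mask, windowBeads = 400)
  # perturb the earliest window's beads only
  idx <- which(mask)
  early <- idx[seq_len(400)]
  x <- exprs(m)
  meta <- channelMeta(m)
  beadChans <- meta$name[!is.na(meta$metal) &
                         meta$metal %in% CytoMonitor:::.EQ_BEAD_METALS]
  x[early, beadChans] <- x[early, beadChans] * 2
  m2 <- new("EventMatrix", exprs = x, channelMeta = meta, time = m@time,
            scale = "raw", scaleFactors = numeric(0))
  model2 <- fitBeadModel(m2, mask, windowBeads = 400)
  late <- acqTime(m) > model$windows$time[2]
  # the perturbation moves the first window's factor strongly; late
  # factors change only through the global reference, i.e. by a common
  # scale, so their ratio to the unperturbed factors is constant
  expect_gt(abs(model2$windows$factor[1] - model$windows$factor[1]), 0.2)
  rel <- model2$factors[late] / model$factors[late]
  expect_lt(max(abs(rel / mean(rel) - 1)), 0.01)
})

test_that("debarcoding assigns clean pools and rejects union patterns", {
  tmpl <- fxPbmcTemplates()
  sch <- list(s1 = c("102Pd", "104Pd", "105Pd"),
              s2 = c("104Pd", "106Pd", "110Pd"),
              s3 = c("102Pd", "108Pd", "110Pd"))
  cfgs <- list(simConfig(1500, 41, tmpl), simConfig(1500, 42, tmpl),
               simConfig(1500, 43, tmpl))
  pool <- simulateBarcodedPool(cfgs, sch, doubletFraction = 0.02, seed = 44)
  db <- debarcode(pool$matrix, sch, cutoff = 0.1)
  nd <- pool$truth$sample != "doublet"
  expect_gt(mean(db$assignment[nd] == pool$truth$sample[nd]), 0.99)
  # cross-sample doublets carry a union pattern: no valid 3-of-6 match
  expect_gt(mean(db$assignment[!nd] == "unassigned"), 0.85)
  expect_true(all(db$separation >= 0))
  # yield + unassigned fraction telescopes to 1
  expect_equal(sum(db$yield), 1)
  expect_error(debarcode(pool$matrix, sch, cutoff = 1.5), "\\[0, 1\\]")

  # noiseless codes, cutoff 0: assignment equals ground truth exactly
  meta <- channelMeta(pool$matrix)
  bc <- meta$name[meta$class == "barcode"]
  x <- exprs(pool$matrix)
  x[, bc] <- 0
  for (nm in names(sch)) {
    rows <- pool$truth$sample == nm
    on <- meta$name[!is.na(meta$metal) & meta$metal %in% sch[[nm]]]
    x[rows, on] <- 1000
  }
  clean <- new("EventMatrix", exprs = x, channelMeta = meta,
               time = pool$matrix@time, scale = "raw",
               scaleFactors = numeric(0))
  db0 <- debarcode(clean, sch, cutoff = 0)
  expect_identical(db0$assignment[nd], pool$truth$sample[nd])
})
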