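test_that("antigen coverage counts positives per cell", {
  # an event with exactly 4 antigens above cutoff counts 4
  vals <- matrix(0.2, 2, 5,
                 dimnames = list(NULL, c("CD45", "CD3", "CD4", "CD27",
                                         "CD19")))
  vals[1, 1:4] <- 4.5
  m <- makeMatrix(vals, antigens = colnames(vals))
  cov <- antigenCoverage(m, fxCutoffs(), k = 4)
  expect_identical(cov$counts[1], 4L)
  expect_identical(cov$counts[2], 0L)
  expect_identical(cov$fraction_ge_k, 0.5)

  # cutoffs at infinity: every count is zero
  inf <- fxCutoffs()
  inf$primary[] <- Inf
  expect_true(all(antigenCoverage(m, inf)$counts == 0L))

  # missing cutoff errors with the antigen's name
  cut <- fxCutoffs()
  cut <- cut[cut$channel != "CD56", ]
  expect_error(antigenCoverage(m, cut), "CD56")

  # invariant under channel permutation
  g <- fxPbmcGated()
  sub <- g$pregated[1:2000]
  perm <- sample(ncol(sub))
  shuf <- new("EventMatrix", exprs = exprs(sub)[, perm],
              channelMeta = channelMeta(sub)[perm, ],
              time = acqTime(sub), scale = transformScale(sub),
              scaleFactors = numeric(0))
  expect_identical(antigenCoverage(sub, fxCutoffs())$counts,
                   antigenCoverage(shuf, fxCutoffs())$counts)
})

test_that("replicate regression recovers exact linear relations", {
  f <- c(0.4, 0.25, 0.2, 0.1, 0.05)
  r <- replicateRegression(f, f)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  r2 <- replicateRegression(f, 2 * f)
  expect_equal(r2$r, 1)
  expect_equal(r2$slope, 2)
  expect_error(replicateRegression(f, f[1:3]), "same length")
  expect_error(replicateRegression(f[1:2], f[1:2]), "at least 3")
  expect_error(replicateRegression(rep(0.2, 5), f), "zero variance")
})

test_that("sample-profile clustering groups replicates", {
  m <- rbind(a = c(0.5, 0.3, 0.2), b = c(0.5, 0.3, 0.2),
             c = c(0.1, 0.1, 0.8))
  hc <- clusterSampleProfiles(m)
  expect_equal(hc$height[1], 0)              # duplicated rows merge first
  expect_identical(hc$merge[2, 2], 1L)       # the distant sample joins last
  sib <- leafSiblings(hc)
  expect_identical(sort(c(sib$a, sib$b)), c("a", "b"))
  expect_error(clusterSampleProfiles(m[1, , drop = FALSE]), "2 samples")
  m[1, 1] <- NaN
  expect_error(clusterSampleProfiles(m), "non-finite")

  # 5 simulated donors x 2 replicates: >= 4/5 donor pairs are siblings
  set.seed(81)
  tmpl <- fxPbmcTemplates()
  freqs <- NULL
  for (d in 1:5) {
    f <- vapply(tmpl, `[[`, numeric(1), "frequency")
    f <- stats::plogis(stats::qlogis(f) + rnorm(length(f), 0, 0.3))
    f <- f / sum(f)
    td <- tmpl
    for (i in seq_along(td)) td[[i]]$frequency <- f[i]
    pair <- simulateReplicatePair(
      simConfig(8000, seed = 81 + d, templates = td, name = paste0("D", d)),
      technicalNoiseSd = 0.05)
    for (rep_ in c("a", "b")) {
      sim <- pair[[rep_]]
      tr <- arcsinhTransform(sim$matrix)
      pg <- pregate(tr, fxCutoffs())
      gr <- suppressWarnings(applyGating(tr[pg$mask], fxTree(), fxCutoffs(),
                                         sampleId = paste0("D", d, rep_)))
      freqs <- rbind(freqs, leafFrequencies(gr))
      rownames(freqs)[nrow(freqs)] <- paste0("D", d, rep_)
    }
  }
  hc <- clusterSampleProfiles(freqs)
  sib <- leafSiblings(hc)
  donorPair <- substr(sib$a, 1, 2) == substr(sib$b, 1, 2)
  expect_gte(sum(donorPair), 4)
})

test_that("bootstrap SEM of the median behaves as documented", {
  expect_identical(bootstrapSemMedian(rep(3, 20), seed = 1)$sem, 0)
  v <- 1:100
  b <- bootstrapSemMedian(v, nBoot = 4000, seed = 2)
  # asymptotic SE of a uniform sample median: 1 / (2 f(m) sqrt(n))
  theo <- (max(v) - min(v)) / (2 * sqrt(length(v)))
  expect_lt(abs(b$sem - theo) / theo, 0.15)
  b2 <- bootstrapSemMedian(v, nBoot = 4000, seed = 3)
  expect_lt(abs(b$sem - b2$sem) / b$sem, 0.10)
  expect_error(bootstrapSemMedian(1, seed = 1), "at least 2")
  expect_error(bootstrapSemMedian(v, nBoot = 1), "nBoot")
})

test_that("agreement metrics match their closed forms", {
  # direct formula evaluation: TP=90, FN=10, FP=5, TN=895
  mkLabels <- function(tp, fp, fn, tn) {
    a <- c(rep("X", tp), rep("X", fn), rep("o", fp), rep("o", tn))
    b <- c(rep("X", tp), rep("o", fn), rep("X", fp), rep("o", tn))
    list(a = a, b = b)
  }
  l <- mkLabels(90, 5, 10, 895)
  rep_ <- agreement(l$a, l$b, populations = "X")$perPopulation
  expect_equal(rep_$mcc, (90 * 895 - 5 * 10) /
                 sqrt(95) / sqrt(100) / sqrt(900) / sqrt(905))
  expect_equal(rep_$mcc, 0.9151, tolerance = 1e-3)
  expect_equal(rep_$precision, 90 / 95)
  expect_equal(rep_$recall, 0.9)

  # perfect agreement
  g <- agreement(l$a, l$a)
  expect_true(all(g$perPopulation$mcc == 1))
  expect_identical(unname(g$macro[["f1"]]), 1)

  # independent random labels: MCC near 0
  set.seed(9)
  a <- sample(c("X", "o"), 20000, replace = TRUE)
  b <- sample(c("X", "o"), 20000, replace = TRUE)
  expect_lt(abs(agreement(a, b, "X")$perPopulation$mcc), 0.05)

  expect_error(agreement(l$a, l$b[1:10]), "same length")
})

test_that("MCC equals a brute-force oracle on all small tables", {
  # enumeration oracle: every 2x2 table with total <= 20, computed from
  # label vectors through the full agreement() path
  bruteMCC <- function(tp, fp, fn, tn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  for (n in c(1, 2, 3, 5, 8, 13, 20)) {
    parts <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$tn <- n - rowSums(parts)
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      a <- c(rep("X", p$tp + p$fn), rep("o", p$fp + p$tn))
      b <- c(rep("X", p$tp), rep("o", p$fn), rep("X", p$fp), rep("o", p$tn))
      got <- agreement(a, b, populations = "X")$perPopulation$mcc
      expect_equal(got, bruteMCC(p$tp, p$fp, p$fn, p$tn), tolerance = 1e-12)
    }
  }
  # symmetry under swapping the two labelings
  set.seed(10)
  a <- sample(c("X", "o", "z"), 500, replace = TRUE)
  b <- sample(c("X", "o", "z"), 500, replace = TRUE)
  expect_equal(agreement(a, b)$perPopulation$mcc,
               agreement(b, a)$perPopulation$mcc)
})

test_that("BH correction matches a brute-force step-up on small inputs", {
  bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    # step-up from the largest p-value
    running <- 1
    for (i in n:1) {
      running <- min(running, p[o[i]] * n / i)
      adj[o[i]] <- running
    }
    adj
  }
  set.seed(11)
  for (rep_ in 1:20) {
    n <- sample(1:20, 1)
    p <- runif(n)^sample(c(1, 2, 0.5), 1)
    expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  }
  # the DAResult fdr column is BH of its p column with monotonicity
  counts <- matrix(rpois(8 * 10, 50), nrow = 8,
                   dimnames = list(letters[1:8], NULL))
  da <- differentialAbundance(counts, rep(c("A", "B"), each = 5))
  expect_equal(da$fdr, p.adjust(da$p, "BH"))
  expect_true(all(da$fdr >= da$p - 1e-12))
})

test_that("differential abundance handles degenerate inputs", {
  counts <- matrix(rep(c(100, 50, 10, 200), 8), nrow = 4,
                   dimnames = list(c("w", "x", "y", "z"), NULL))
  da <- differentialAbundance(counts, rep(c("A", "B"), each = 4))
  expect_true(all(abs(da$log2fc) < 1e-8))
  expect_true(all(da$fdr > 1 - 1e-8))

  z <- counts
  z["y", 1:4] <- 0L
  z["y", 5:8] <- 0L
  da2 <- differentialAbundance(z, rep(c("A", "B"), each = 4))
  expect_true(da2$flagged[da2$population == "y"])
  expect_identical(da2$p[da2$population == "y"], 1)

  expect_error(differentialAbundance(counts, rep("A", 8)), "two groups")
  expect_error(differentialAbundance(counts, rep(c("A", "B", "C"),
                                                 c(3, 3, 2))), "two groups")
})

test_that("differential abundance is invariant to per-sample scaling", {
  set.seed(13)
  co <- simulateCohort(nSamples = 28, seed = 500, eventData = FALSE)
  counts <- apply(co$trueFreq, 2, function(p) rmultinom(1, 10000, p))
  rownames(counts) <- rownames(co$trueFreq)
  da1 <- differentialAbundance(counts, co$metadata$group)
  scaled <- counts
  scaled[, 1] <- counts[, 1] * 5L   # one sample acquired 5x deeper
  da2 <- differentialAbundance(scaled, co$metadata$group)
  expect_lt(max(abs(da1$log2fc - da2$log2fc)), 0.25)
  expect_gt(cor(da1$log2fc, da2$log2fc), 0.99)
})

test_that("an exchangeable cohort yields no discoveries at FDR 0.05", {
  # effect-free cohorts: the FDR-level discovery rate must be controlled
  # (at most a few runs of 40 with any FDR < 0.05 population)
  set.seed(14)
  disc <- logical(40)
  for (r in seq_along(disc)) {
    co <- simulateCohort(nSamples = 28, seed = 40000 + r,
                         eventData = FALSE, effectTable = NULL)
    counts <- apply(co$trueFreq, 2, function(p) rmultinom(1, 15000, p))
    rownames(counts) <- rownames(co$trueFreq)
    da <- differentialAbundance(counts, co$metadata$group)
    disc[r] <- any(da$fdr < 0.05)
  }
  expect_gte(mean(!disc), 0.95)
})

test_that("the NB Wald ranking agrees with edgeR on a strong effect", {
  skip_if_not_installed("edgeR")
  set.seed(15)
  co <- simulateCohort(nSamples = 28, seed = 600, eventData = FALSE)
  counts <- apply(co$trueFreq, 2, function(p) rmultinom(1, 15000, p))
  rownames(counts) <- rownames(co$trueFreq)
  da <- differentialAbundance(counts, co$metadata$group)
  # align edgeR's coefficient with ours: GvHD relative to noGvHD
  grp <- factor(co$metadata$group, levels = c("noGvHD", "GvHD"))
  y <- edgeR::DGEList(counts = counts, group = grp)
  y <- edgeR::estimateDisp(y, model.matrix(~grp))
  fit <- edgeR::glmFit(y, model.matrix(~grp))
  lrt <- edgeR::glmLRT(fit)
  tab <- lrt$table[da$population, ]
  # the two routes agree on the direction and the leading hit
  expect_gt(cor(da$log2fc, tab$logFC), 0.95)
  expect_identical(da$population[which.min(da$p)],
                   rownames(tab)[which.min(tab$PValue)])
})
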