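# helper: a percentile-normalized matrix with two well-separated blobs on
# CD3/CD19 (n events, fraction f in blob 2)
twoBlobMatrix <- function(n = 2000, f = 0.5, seed = 71) {
  set.seed(seed)
  lab <- runif(n) < f
  vals <- cbind(CD3 = ifelse(lab, 0.1, 0.9) + rnorm(n, 0, 0.03),
                CD19 = ifelse(lab, 0.9, 0.1) + rnorm(n, 0, 0.03))
  m <- makeMatrix(pmax(vals, 0), antigens = c("CD3", "CD19"))
  m@scale <- "arcsinh_p995"
  list(matrix = m, lab = lab)
}

test_that("SOM training is deterministic and converges on degenerate data", {
  tb <- twoBlobMatrix()
  m1 <- trainSOM(tb$matrix, grid = c(3, 3), seed = 5,
                 channels = c("CD3", "CD19"))
  m2 <- trainSOM(tb$matrix, grid = c(3, 3), seed = 5,
                 channels = c("CD3", "CD19"))
  expect_identical(m1@codebook, m2@codebook)
  expect_identical(m1@mapping, m2@mapping)

  # a single tight Gaussian: every codebook vector near the center
  set.seed(72)
  g <- makeMatrix(cbind(CD3 = rnorm(3000, 0.5, 0.05)), antigens = "CD3")
  g@scale <- "arcsinh_p995"
  sm <- trainSOM(g, grid = c(2, 2), seed = 1, channels = "CD3")
  expect_true(all(abs(sm@codebook[, "CD3"] - 0.5) < 3 * 0.05))

  expect_error(trainSOM(g, grid = c(30, 30), seed = 1, channels = "CD3"),
               "too few events")
  expect_error(trainSOM(g, grid = c(2, 2), seed = 1, channels = "CD99"),
               "not in matrix")
})

test_that("separable blobs are resolved by a 2x1 grid", {
  tb <- twoBlobMatrix()
  sm <- trainSOM(tb$matrix, grid = c(2, 1), seed = 3,
                 channels = c("CD3", "CD19"))
  node2 <- sm@mapping == which.max(sm@codebook[, "CD19"])
  expect_identical(mean(node2 == tb$lab), 1)
})

test_that("metaclustering cuts the codebook dendrogram", {
  tb <- twoBlobMatrix()
  sm <- trainSOM(tb$matrix, grid = c(4, 4), seed = 3,
                 channels = c("CD3", "CD19"))
  # k = node count: every node is its own metacluster
  expect_identical(sort(unique(metacluster(sm, 16))), 1:16)
  expect_identical(unique(metacluster(sm, 1)), 1L)
  m2 <- metacluster(sm, 2)
  evMeta <- m2[sm@mapping]
  expect_identical(length(unique(tapply(tb$lab, evMeta, mean))), 2L)
  expect_true(all(tapply(tb$lab, evMeta, mean) %in% c(0, 1)))
  expect_error(metacluster(sm, 0), "k must lie")
  expect_error(metacluster(sm, 17), "k must lie")
})

test_that("annotation assigns marker-concordant labels", {
  g <- fxPbmcGated()
  pn <- percentileNormalize(g$pregated)
  cuts <- rescaleCutoffs(fxCutoffs(), pn)
  model <- trainSOM(pn, grid = c(10, 10), seed = 7)
  meta <- metacluster(model, 25)
  lab <- annotateClusters(pn, model, meta, fxPbmcLineages(), cuts)
  labels <- eventLabels(model, lab)
  # lineage-level agreement with ground truth >= 95%
  lin <- c("T cells", "B cells", "NK cells", "Monocytes", "cDC", "pDC",
           "Basophils")
  idx <- CytoMonitor:::.lineageIndex(fxPbmcLineages())
  toLineage <- function(x) {
    up <- vapply(x, function(nm) {
      if (nm %in% lin) return(nm)
      anc <- CytoMonitor:::.ancestors(nm, idx$parent)
      hit <- intersect(anc, lin)
      if (length(hit)) hit[1] else nm
    }, character(1))
    unname(up)
  }
  truthLin <- toLineage(g$truth$label)
  predLin <- toLineage(labels)
  expect_gt(mean(predLin == truthLin), 0.95)

  # an all-zero median profile is Unassigned
  zero <- makeMatrix(matrix(0, 200, 2), antigens = c("CD3", "CD19"))
  zero@scale <- "arcsinh_p995"
  zm <- trainSOM(zero, grid = c(2, 2), seed = 1, channels = c("CD3", "CD19"))
  zl <- annotateClusters(zero, zm, rep(1L, 4), fxPbmcLineages(), cuts)
  expect_identical(unique(zl@metaLabel), "Unassigned")
})

test_that("annotation is deterministic given model, cutoffs and floor", {
  g <- fxPbmcGated()
  pn <- percentileNormalize(g$pregated[1:5000])
  cuts <- rescaleCutoffs(fxCutoffs(), pn)
  model <- trainSOM(pn, grid = c(6, 6), seed = 9)
  meta <- metacluster(model, 12)
  l1 <- annotateClusters(pn, model, meta, fxPbmcLineages(), cuts)
  l2 <- annotateClusters(pn, model, meta, fxPbmcLineages(), cuts)
  expect_identical(l1@metaLabel, l2@metaLabel)
  # labels come from the lineage vocabulary
  expect_true(all(l1@metaLabel %in%
                  c(lineageNames(fxPbmcLineages()), "Unassigned")))
})

test_that("subclustering refines a lineage and leaves others untouched", {
  g <- fxPbmcGated()
  pn <- percentileNormalize(g$pregated)
  cuts <- rescaleCutoffs(fxCutoffs(), pn)
  model <- trainSOM(pn, grid = c(10, 10), seed = 7)
  meta <- metacluster(model, 25)
  labeling <- annotateClusters(pn, model, meta, fxPbmcLineages(), cuts)
  labels <- eventLabels(model, labeling)
  refined <- subcluster(pn, labels, "B cells", fxPbmcLineages(), cuts,
                        seed = 7)
  # locality: non-B labels unchanged
  d <- fxPbmcLineages()@definitions
  idx <- CytoMonitor:::.lineageIndex(fxPbmcLineages())
  bsub <- c("B cells", idx$children[["B cells"]])
  outside <- !(labels %in% bsub)
  expect_identical(refined[outside], labels[outside])
  # CD27- and CD27+ subsets recovered within tolerance of ground truth
  truth <- g$truth$label
  for (nm in c("CD27- B cells", "CD27+ B cells")) {
    tru <- mean(truth == nm)
    rec <- mean(refined == nm)
    expect_lt(abs(rec - tru), tol4se(tru, length(truth)) + 0.15 * tru)
  }
  # too few events: warning and no-op
  few <- labels
  few[few %in% bsub] <- "Unassigned"
  few[1:30] <- "B cells"
  expect_warning(r2 <- subcluster(pn, few, "B cells", fxPbmcLineages(),
                                  cuts, seed = 7, minEvents = 200),
                 "too few events")
  expect_identical(r2, few)
})
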