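# Panel-coverage QC, reproducibility metrics, label agreement, bootstrap
# SEM of medians, and differential abundance.

#' Number of positive antigens per cell
#'
#' Counts, per event, the antibody antigens whose transformed intensity is
#' at or above the primary cutoff, and summarizes the per-cell counts:
#' the median and the fraction of cells with at least \code{k} positive
#' antigens, overall and stratified by a label vector when supplied.
#'
#' @param matrix a transformed \linkS4class{EventMatrix}.
#' @param cutoffs cutoff table covering every antibody antigen of the
#'   matrix (on the matrix scale).
#' @param k threshold for \code{fraction_ge_k}; default 4.
#' @param by optional character vector of per-event lineage labels for
#'   stratified reporting.
#' @return list with \code{counts} (integer per event), \code{median},
#'   \code{fraction_ge_k}, \code{k}, and (when \code{by} is given)
#'   \code{byLineage} (data.frame: lineage, n, median, fraction_ge_k).
#' @export
antigenCoverage <- function(matrix, cutoffs, k = 4L, by = NULL) {
  stopifnot(is(matrix, "EventMatrix"))
  if (matrix@scale == "raw")
    stop("antigenCoverage expects a transformed matrix", call. = FALSE)
  cols <- .antigenCols(matrix)
  cut <- vapply(names(cols), function(a) .cutoffFor(cutoffs, a), numeric(1))
  pos <- sweep(matrix@exprs[, cols, drop = FALSE], 2, cut, ">=")
  counts <- as.integer(rowSums(pos))
  out <- list(counts = counts, median = median(counts),
              fraction_ge_k = mean(counts >= k), k = as.integer(k))
  if (!is.null(by)) {
    if (length(by) != length(counts))
      stop("'by' must have one label per event", call. = FALSE)
    sp <- split(counts, by)
    out$byLineage <- data.frame(
      lineage = names(sp), n = lengths(sp),
      median = vapply(sp, median, numeric(1)),
      fraction_ge_k = vapply(sp, function(v) mean(v >= k), numeric(1)),
      row.names = NULL)
  }
  out
}

#' Linear regression between replicate frequency vectors
#'
#' Ordinary least squares of \code{freqB} on \code{freqA}, pooled over
#' populations (and donors when the vectors are concatenated across
#' donors), with the Pearson correlation and the two-sided p-value of the
#' slope.
#'
#' @param freqA,freqB numeric frequency vectors over the same populations
#'   (length >= 3).
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{p}.
#' @export
replicateRegression <- function(freqA, freqB) {
  if (length(freqA) != length(freqB))
    stop("frequency vectors must have the same length", call. = FALSE)
  if (length(freqA) < 3L)
    stop("at least 3 populations are required", call. = FALSE)
  if (sd(freqA) == 0)
    stop("zero variance in the predictor frequencies", call. = FALSE)
  fit <- lm(freqB ~ freqA)
  # an exactly linear relation triggers lm's perfect-fit warning; the
  # coefficients and r are still what callers need
  s <- suppressWarnings(summary(fit))$coefficients
  list(r = cor(freqA, freqB), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p = unname(s["freqA", "Pr(>|t|)"]))
}

#' Hierarchical clustering of sample frequency profiles
#'
#' @param freqMatrix samples x populations matrix of frequencies.
#' @param linkage agglomeration method (default "complete").
#' @param metric distance metric (default "euclidean").
#' @return an \code{hclust} object over the samples.
#' @export
clusterSampleProfiles <- function(freqMatrix, linkage = "complete",
                                  metric = "euclidean") {
  if (is.null(dim(freqMatrix)) || nrow(freqMatrix) < 2L)
    stop("at least 2 samples are required", call. = FALSE)
  if (any(!is.finite(freqMatrix)))
    stop("frequency matrix contains non-finite values", call. = FALSE)
  hclust(dist(freqMatrix, method = metric), method = linkage)
}

#' Pairs of samples that are mutual nearest leaves of a dendrogram
#'
#' Two leaves are siblings when they are merged directly with each other
#' (a leaf-leaf junction); used to test whether technical replicates of
#' the same donor group together.
#'
#' @param hc an \code{hclust} object.
#' @return data.frame with columns \code{a}, \code{b} (leaf labels).
#' @export
leafSiblings <- function(hc) {
  m <- hc$merge
  pair <- m[m[, 1] < 0 & m[, 2] < 0, , drop = FALSE]
  data.frame(a = hc$labels[-pair[, 1]], b = hc$labels[-pair[, 2]],
             stringsAsFactors = FALSE)
}

#' Bootstrap standard error of the median
#'
#' The standard deviation of the median over \code{nBoot} resamples with
#' replacement; deterministic given the seed.
#'
#' @param values numeric vector (length >= 2).
#' @param nBoot number of bootstrap resamples; default 1000.
#' @param seed integer seed.
#' @return list with \code{median} and \code{sem}.
#' @export
bootstrapSemMedian <- function(values, nBoot = 1000L, seed = 1L) {
  if (length(values) < 2L)
    stop("at least 2 values are required", call. = FALSE)
  if (nBoot < 2L)
    stop("nBoot must be >= 2", call. = FALSE)
  set.seed(seed)
  meds <- vapply(seq_len(nBoot), function(i)
    median(sample(values, replace = TRUE)), numeric(1))
  list(median = median(values), sem = sd(meds))
}

.mcc <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Per-population agreement between two labelings
#'
#' One-vs-rest binarization of both labelings per population: confusion
#' counts, precision, recall, F1 and the Matthews correlation coefficient
#' (MCC; defined as 0 when any marginal factor of its denominator is 0),
#' plus macro means over the populations.
#'
#' @param labelsA,labelsB character label vectors of equal length
#'   (e.g. manual gating vs clustering annotation).
#' @param populations populations to evaluate; default: all labels present
#'   in either vector except \code{"Unassigned"}.
#' @return list with \code{perPopulation} (data.frame: population, tp, fp,
#'   fn, tn, precision, recall, f1, mcc) and \code{macro} (named means).
#' @export
agreement <- function(labelsA, labelsB, populations = NULL) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have the same length", call. = FALSE)
  if (is.null(populations))
    populations <- setdiff(sort(unique(c(labelsA, labelsB))), "Unassigned")
  n <- length(labelsA)
  rows <- lapply(populations, function(p) {
    a <- labelsA == p; b <- labelsB == p
    tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(population = p, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f1 = f1,
               mcc = .mcc(tp, fp, fn, tn), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(perPopulation = per,
       macro = c(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), mcc = mean(per$mcc)))
}

# method-of-moments NB dispersion for one population given fitted means,
# with an n/(n - p) degrees-of-freedom correction for the two fitted
# coefficients (uncorrected moments underestimate the dispersion and make
# the Wald test anti-conservative at cohort-sized n)
.momDispersion <- function(y, mu, p = 2L) {
  n <- length(y)
  num <- sum((y - mu)^2 - mu) * n / max(1L, n - p)
  den <- sum(mu^2)
  max(0, num / den)
}

#' Differential abundance of population counts between two groups
#'
#' Per population, a negative-binomial GLM of the per-sample counts with a
#' log(sample total) offset and a group indicator.  The NB dispersion is a
#' per-population method-of-moments estimate shrunk toward the cohort
#' median dispersion (weight \code{shrink}); the group coefficient is
#' tested with a Wald statistic referred to a t distribution with
#' (number of samples - 2) degrees of freedom, and p-values are corrected
#' across populations by Benjamini-Hochberg.  Samples from multiple time
#' points are pooled.  A population with all-zero counts in either group
#' is flagged and assigned p = 1 by convention.
#'
#' @param cohort a \link[SummarizedExperiment]{SummarizedExperiment} with
#'   a \code{counts} assay (populations x samples) as produced by
#'   \code{\link{frequencyTable}}, or a plain counts matrix.
#' @param groupCol name of the column-metadata column holding the group
#'   labels (exactly two groups, each with >= 2 samples), or a vector of
#'   group labels when \code{cohort} is a matrix.
#' @param groups optional length-2 character vector fixing the order
#'   (log2 fold change is group 1 relative to group 2).
#' @param shrink dispersion shrinkage weight toward the cohort median in
#'   [0, 1]; default 0.5.
#' @return data.frame with one row per population: \code{population},
#'   \code{log2fc}, \code{dispersion}, \code{stat}, \code{p}, \code{fdr},
#'   \code{flagged}.
#' @export
differentialAbundance <- function(cohort, groupCol = "group", groups = NULL,
                                  shrink = 0.5) {
  if (is(cohort, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(cohort, "counts")
    grp <- SummarizedExperiment::colData(cohort)[[groupCol]]
    if (is.null(grp))
      stop("no '", groupCol, "' column in the cohort metadata", call. = FALSE)
  } else {
    counts <- cohort
    grp <- groupCol
  }
  grp <- as.character(grp)
  if (length(grp) != ncol(counts))
    stop("one group label per sample is required", call. = FALSE)
  lev <- if (is.null(groups)) sort(unique(grp)) else groups
  if (length(lev) != 2L || any(table(factor(grp, lev)) < 2L))
    stop("exactly two groups with >= 2 samples each are required",
         call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("sample totals must be positive", call. = FALSE)
  g <- factor(grp, levels = rev(lev))  # coefficient: lev[1] vs lev[2]
  off <- log(totals)
  nPop <- nrow(counts)
  fits <- vector("list", nPop)
  phi <- numeric(nPop)
  flagged <- logical(nPop)
  for (i in seq_len(nPop)) {
    y <- counts[i, ]
    if (any(vapply(split(y, g), function(v) all(v == 0), logical(1)))) {
      flagged[i] <- TRUE
      phi[i] <- NA_real_
      next
    }
    pfit <- glm(y ~ g + offset(off), family = poisson())
    phi[i] <- .momDispersion(y, fitted(pfit))
  }
  phiMed <- median(phi, na.rm = TRUE)
  if (!is.finite(phiMed)) phiMed <- 0
  df <- length(grp) - 2L
  out <- data.frame(population = rownames(counts), log2fc = 0,
                    dispersion = NA_real_, stat = 0, p = 1,
                    flagged = flagged, stringsAsFactors = FALSE)
  for (i in seq_len(nPop)) {
    if (flagged[i]) next
    y <- counts[i, ]
    disp <- (1 - shrink) * phi[i] + shrink * phiMed
    out$dispersion[i] <- disp
    theta <- if (disp < 1e-8) 1e8 else 1 / disp
    fit <- suppressWarnings(
      glm(y ~ g + offset(off), family = MASS::negative.binomial(theta)))
    beta <- coef(fit)[2]
    # the NB variance function already carries the dispersion, so the
    # covariance is taken at unit GLM dispersion (summary.glm would
    # otherwise rescale it by a Pearson estimate)
    se <- sqrt(diag(summary(fit, dispersion = 1)$cov.scaled))[2]
    # quasi-likelihood guard: residual overdispersion beyond the fitted NB
    # variance (e.g. heavy-tailed between-sample mixing) scales the SE up
    mu <- fitted(fit)
    x2 <- sum((y - mu)^2 / (mu * (1 + disp * mu)))
    se <- se * sqrt(max(1, x2 / df))
    out$log2fc[i] <- unname(beta) / log(2)
    out$stat[i] <- unname(beta / se)
    out$p[i] <- 2 * pt(-abs(out$stat[i]), df = df)
  }
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
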