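# Bead-based drift correction and barcode deconvolution (applied on the
# raw scale, before any gating).

# arcsinh view of selected raw columns, for threshold decisions
.asinhCols <- function(matrix, cols) asinh(matrix@exprs[, cols, drop = FALSE] /
                                           .COFACTOR)

# columns (by $PnN name) of the EQ bead metals present in the matrix
.beadChannels <- function(matrix, beadMetals = .EQ_BEAD_METALS) {
  meta <- matrix@channelMeta
  hit <- !is.na(meta$metal) & meta$metal %in% beadMetals
  if (!any(meta$class[hit] == "bead"))
    stop("no bead channel present in the matrix", call. = FALSE)
  meta$name[hit]
}

#' Identify calibration-bead events
#'
#' EQ calibration beads are positive in \emph{all} bead channels and
#' DNA-negative.  Events positive in every bead channel but also
#' DNA-positive are bead-cell doublets and are excluded from the returned
#' bead mask (pre-gating removes them from the cell fraction separately).
#'
#' @param matrix raw-scale \linkS4class{EventMatrix}.
#' @param beadMetals metals that light up on the beads (default: the EQ
#'   four-element metals plus 140Ce).
#' @param cutoffs cutoff table supplying the \code{Bead} and \code{DNA}
#'   thresholds (arcsinh scale).
#' @return logical per-event bead mask.
#' @export
identifyBeads <- function(matrix, beadMetals = .EQ_BEAD_METALS,
                          cutoffs = defaultCutoffs()) {
  stopifnot(is(matrix, "EventMatrix"))
  bc <- .beadChannels(matrix, beadMetals)
  beadCut <- .cutoffFor(cutoffs, "Bead")
  dnaCut <- .cutoffFor(cutoffs, "DNA")
  y <- .asinhCols(matrix, bc)
  allHigh <- rowSums(y >= beadCut) == length(bc)
  meta <- matrix@channelMeta
  dna <- .asinhCols(matrix, meta$name[meta$class == "dna"])
  dnaPos <- rowSums(dna >= dnaCut) == ncol(dna)
  allHigh & !dnaPos
}

#' Fit a bead drift model
#'
#' Splits the bead events into consecutive acquisition-time windows of
#' \code{windowBeads} beads each and computes, per window, the median raw
#' intensity of every bead channel.  The per-window correction factor is
#' the median over bead channels of (global bead median / window median);
#' per-event factors are obtained by linear interpolation between window
#' centers (constant extrapolation outside).
#'
#' @param matrix raw-scale \linkS4class{EventMatrix}.
#' @param beadMask logical bead mask (\code{\link{identifyBeads}}).
#' @param windowBeads beads per window (default 500; windows are defined
#'   in events, not seconds, so pauses in acquisition do not distort the
#'   fit).
#' @param beadMetals bead channel metals.
#' @return a bead model: list with \code{windows} (data.frame of window
#'   center time and factor), \code{windowMedians}, \code{reference},
#'   \code{factors} (per event of \code{matrix}) and \code{identity}
#'   (TRUE when no correction could be fitted).
#' @export
fitBeadModel <- function(matrix, beadMask, windowBeads = 500,
                         beadMetals = .EQ_BEAD_METALS) {
  stopifnot(is(matrix, "EventMatrix"))
  bc <- .beadChannels(matrix, beadMetals)
  n <- nEvents(matrix)
  identityModel <- function() list(
    windows = data.frame(time = range(matrix@time), factor = c(1, 1)),
    windowMedians = NULL, reference = NULL,
    factors = rep(1, n), identity = TRUE)
  idx <- which(beadMask)
  if (!length(idx)) {
    warning("no bead events found; applying identity normalization",
            call. = FALSE)
    return(identityModel())
  }
  # windowBeads is a target size; with few beads fall back to two windows
  # so short acquisitions still get a (coarse) drift estimate
  nw <- max(2L, floor(length(idx) / windowBeads))
  win <- cut(seq_along(idx), breaks = nw, labels = FALSE)
  keep <- tabulate(win, nw) >= 10L
  if (sum(keep) < 2L) {
    warning("fewer than 2 bead windows with >= 10 beads; ",
            "applying identity normalization", call. = FALSE)
    return(identityModel())
  }
  raw <- matrix@exprs[idx, bc, drop = FALSE]
  med <- vapply(seq_len(nw), function(w)
    apply(raw[win == w, , drop = FALSE], 2, median), numeric(length(bc)))
  med <- t(med)  # windows x channels
  reference <- apply(raw, 2, median)
  ctr <- vapply(seq_len(nw), function(w) median(matrix@time[idx][win == w]),
                numeric(1))
  zero <- apply(med <= 0, 1, any)
  use <- keep & !zero
  if (any(zero & keep))
    message("dropping ", sum(zero & keep),
            " bead window(s) with zero median from interpolation")
  if (sum(use) < 2L) {
    warning("not enough usable bead windows; applying identity normalization",
            call. = FALSE)
    return(identityModel())
  }
  fac <- vapply(which(use), function(w)
    median(reference / med[w, ]), numeric(1))
  ev <- approx(ctr[use], fac, xout = matrix@time, rule = 2)$y
  list(windows = data.frame(time = ctr[use], factor = fac),
       windowMedians = med[use, , drop = FALSE], reference = reference,
       factors = ev, identity = FALSE)
}

#' Bead-normalize a raw event matrix
#'
#' Multiplies every mass channel (antibody, DNA, viability, bead and
#' barcode) by the event's interpolated correction factor, undoing
#' acquisition-time sensitivity drift.  Event count, channel count, time
#' and event length are unchanged; bead channels are corrected too, so a
#' second application is the identity (to within bead sampling noise).
#'
#' @param matrix raw-scale \linkS4class{EventMatrix}.
#' @param model bead model from \code{\link{fitBeadModel}}; if \code{NULL}
#'   one is fitted using \code{beadMask}.
#' @param beadMask logical bead mask; computed with
#'   \code{\link{identifyBeads}} when missing and \code{model} is NULL.
#' @param windowBeads beads per window for the fit.
#' @return list with \code{matrix} (corrected \linkS4class{EventMatrix})
#'   and \code{model}.
#' @export
beadNormalize <- function(matrix, model = NULL, beadMask = NULL,
                          windowBeads = 500) {
  stopifnot(is(matrix, "EventMatrix"))
  if (matrix@scale != "raw")
    stop("beadNormalize expects a raw-scale matrix", call. = FALSE)
  if (is.null(model)) {
    if (is.null(beadMask)) beadMask <- identifyBeads(matrix)
    model <- fitBeadModel(matrix, beadMask, windowBeads)
  }
  meta <- matrix@channelMeta
  mass <- meta$name[!meta$class %in% c("time", "length")]
  x <- matrix@exprs
  x[, mass] <- x[, mass, drop = FALSE] * model$factors
  out <- new("EventMatrix", exprs = x, channelMeta = meta,
             time = matrix@time, scale = "raw", scaleFactors = numeric(0))
  list(matrix = out, model = model)
}

#' Deconvolve a barcoded pool
#'
#' Per event, the barcode channels are rescaled to [0, 1] by within-event
#' ordering ((x - min) / (max - min) on the arcsinh scale); the event is
#' assigned to the scheme code matching its top-k channels when the
#' separation between the k-th and (k+1)-th largest rescaled intensity is
#' at least \code{cutoff}, and is \code{"unassigned"} otherwise
#' (cross-sample doublets carry a union pattern and match no k-of-n code).
#'
#' @param matrix raw-scale \linkS4class{EventMatrix} with barcode channels.
#' @param scheme named list: sample -> barcode metal vector (all length k).
#' @param cutoff separation cutoff in [0, 1]; default 0.1.
#' @return list with \code{assignment} (character per event),
#'   \code{separation} (numeric per event) and \code{yield} (per-sample
#'   assigned fractions, including \code{"unassigned"}).
#' @export
debarcode <- function(matrix, scheme, cutoff = 0.1) {
  stopifnot(is(matrix, "EventMatrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  k <- unique(lengths(scheme))
  if (length(k) != 1L)
    stop("all scheme codes must have the same length", call. = FALSE)
  if (anyDuplicated(vapply(lapply(scheme, sort), paste, character(1),
                           collapse = "|")))
    stop("scheme codes must be distinct", call. = FALSE)
  meta <- matrix@channelMeta
  bcCols <- which(meta$class == "barcode")
  if (!length(bcCols))
    stop("no barcode channels present in the matrix", call. = FALSE)
  bcMetals <- meta$metal[bcCols]
  y <- .asinhCols(matrix, meta$name[bcCols])
  rng <- apply(y, 1, range)
  span <- rng[2, ] - rng[1, ]
  span[span <= 0] <- 1
  ys <- (y - rng[1, ]) / span
  ord <- t(apply(ys, 1, sort, decreasing = TRUE))
  separation <- ord[, k] - if (k < ncol(ys)) ord[, k + 1L] else 0
  codeKey <- vapply(scheme, function(code)
    paste(sort(match(code, bcMetals)), collapse = ","), character(1))
  topk <- apply(ys, 1, function(r)
    paste(sort(order(r, decreasing = TRUE)[seq_len(k)]), collapse = ","))
  assignment <- names(scheme)[match(topk, codeKey)]
  assignment[is.na(assignment) | separation < cutoff] <- "unassigned"
  yield <- table(factor(assignment, levels = c(names(scheme), "unassigned")))
  yield <- setNames(as.numeric(yield) / length(assignment), names(yield))
  list(assignment = assignment, separation = separation, yield = yield)
}
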