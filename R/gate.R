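# Pre-gating chain and hierarchical gating.

#' Build an executable gating tree from a lineage table
#'
#' Converts the sign-based lineage definitions into threshold clauses:
#' \code{pos}/\code{high} become \code{gte_pos}/\code{gte_high} (at or
#' above the primary/secondary cutoff) and \code{neg}/\code{low} become
#' \code{lt_pos}/\code{lte_low}.  The tree is validated against the panel
#' before it is returned.
#'
#' @param lineages a \linkS4class{LineageTable}.
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return a \linkS4class{GatingTree}.
#' @export
gatingTree <- function(lineages, panel = referencePanel()) {
  viol <- validatePanel(panel, lineages)
  if (nrow(viol))
    stop("panel/lineage validation failed: ", viol$message[1],
         if (nrow(viol) > 1) sprintf(" (+%d more)", nrow(viol) - 1L),
         call. = FALSE)
  d <- lineages@definitions
  idx <- .lineageIndex(lineages)
  rel <- c(pos = "gte_pos", high = "gte_high", neg = "lt_pos", low = "lte_low")
  nodes <- lapply(seq_len(nrow(d)), function(i) {
    lev <- c(d$positive[[i]], d$negative[[i]])
    list(name = d$name[i], parent = d$parent[i],
         children = idx$children[[d$name[i]]],
         clauses = data.frame(antigen = names(lev),
                              relation = unname(rel[lev]),
                              stringsAsFactors = FALSE))
  })
  names(nodes) <- d$name
  new("GatingTree", profile = lineages@profile, nodes = nodes)
}

# logical matrix evaluation of one node's clause conjunction
.evalClauses <- function(clauses, x, cols, cutoffs) {
  ok <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(clauses))) {
    a <- clauses$antigen[i]
    v <- x[, cols[[a]]]
    ok <- ok & switch(clauses$relation[i],
      gte_pos  = v >= .cutoffFor(cutoffs, a),
      lt_pos   = v < .cutoffFor(cutoffs, a),
      gte_high = v >= .cutoffFor(cutoffs, a, secondary = TRUE),
      lte_low  = v <= .cutoffFor(cutoffs, a, secondary = TRUE),
      stop("unknown relation ", clauses$relation[i], call. = FALSE))
  }
  ok
}

#' Pre-gate an event matrix
#'
#' Applies the sequential pre-gating chain, recording events-in/events-out
#' per stage: (1) non-beads; (2) DNA+ (both intercalator channels at or
#' above the DNA cutoff); (3) singlets (DNA below the doublet bound and
#' event length below the length cutoff); (4) live (cisplatin at or below
#' the viability cutoff); (5) CD45+; (6) CD235ab/CD61-; (7) a
#' non-neutrophil rule that excludes CD16+ CD14- HLA-DR- CD11b-high events
#' when \code{granulocytes = TRUE} and is a no-op for PBMC-type input.
#'
#' @param matrix an \linkS4class{EventMatrix} on the arcsinh scale.
#' @param cutoffs cutoff table (arcsinh scale) covering the DNA,
#'   Event_length, Viability, Bead, CD45, CD235ab and CD61 thresholds.
#' @param beadMask optional logical bead mask on the same events; when
#'   \code{NULL}, bead-channel positivity is recomputed from the matrix.
#' @param granulocytes declare that the input may contain granulocytes,
#'   enabling the neutrophil-exclusion stage.
#' @return list with \code{mask} (logical per event) and \code{attrition}
#'   (data.frame: stage, events_in, events_out, fraction_removed).
#' @export
pregate <- function(matrix, cutoffs = defaultCutoffs(), beadMask = NULL,
                    granulocytes = FALSE) {
  stopifnot(is(matrix, "EventMatrix"))
  if (!matrix@scale %in% c("arcsinh", "arcsinh_p995"))
    stop("pregate expects a transformed matrix", call. = FALSE)
  meta <- matrix@channelMeta
  x <- matrix@exprs
  cols <- .antigenCols(matrix)
  need <- function(class, stage) {
    j <- which(meta$class == class)
    if (!length(j))
      stop("missing ", class, " channel required by pre-gating stage '",
           stage, "'", call. = FALSE)
    j
  }
  stages <- list()
  mask <- rep(TRUE, nrow(x))
  note <- function(stage, newMask) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, events_in = sum(mask), events_out = sum(newMask),
      fraction_removed = 1 - sum(newMask) / max(1L, sum(mask)))
    mask <<- newMask
  }

  # (1) non-beads: all bead channels high (bead-cell doublets also drop)
  if (is.null(beadMask)) {
    bc <- meta$name[!is.na(meta$metal) & meta$metal %in% .EQ_BEAD_METALS]
    bc <- bc[meta$class[match(bc, meta$name)] %in% c("bead", "antibody")]
    if (!any(meta$class[match(bc, meta$name)] == "bead"))
      need("bead", "non-beads")
    beadish <- rowSums(x[, bc, drop = FALSE] >=
                       .cutoffFor(cutoffs, "Bead")) == length(bc)
  } else beadish <- beadMask
  note("non-beads", mask & !beadish)

  # (2) DNA+
  dnaCols <- need("dna", "DNA+")
  dnaCut <- .cutoffFor(cutoffs, "DNA")
  dnaPos <- rowSums(x[, dnaCols, drop = FALSE] >= dnaCut) == length(dnaCols)
  note("DNA+", mask & dnaPos)

  # (3) singlets
  lenCol <- need("length", "singlets")
  dblBound <- .cutoffFor(cutoffs, "DNA", secondary = TRUE)
  lenCut <- .cutoffFor(cutoffs, "Event_length")
  singlet <- rowSums(x[, dnaCols, drop = FALSE] < dblBound) ==
    length(dnaCols) & x[, lenCol] < lenCut
  note("singlets", mask & singlet)

  # (4) live
  viabCols <- need("viability", "live")
  viabCut <- .cutoffFor(cutoffs, "Viability")
  live <- rowSums(x[, viabCols, drop = FALSE] <= viabCut) == length(viabCols)
  note("live", mask & live)

  # (5) CD45+
  note("CD45+", mask & x[, cols[["CD45"]]] >= .cutoffFor(cutoffs, "CD45"))

  # (6) CD235ab/CD61-
  note("CD235ab/CD61-", mask &
         x[, cols[["CD235ab"]]] < .cutoffFor(cutoffs, "CD235ab") &
         x[, cols[["CD61"]]] < .cutoffFor(cutoffs, "CD61"))

  # (7) non-neutrophils (documented rule; no-op for PBMC-type input)
  if (granulocytes) {
    neut <- x[, cols[["CD16"]]] >= .cutoffFor(cutoffs, "CD16") &
      x[, cols[["CD14"]]] < .cutoffFor(cutoffs, "CD14") &
      x[, cols[["HLA-DR"]]] < .cutoffFor(cutoffs, "HLA-DR") &
      x[, cols[["CD11b"]]] >= .cutoffFor(cutoffs, "CD11b")
    note("non-neutrophils", mask & !neut)
  } else note("non-neutrophils", mask)

  list(mask = mask, attrition = do.call(rbind, stages))
}

#' Apply a hierarchical gating tree
#'
#' Depth-first predicate evaluation: starting from the root, an event
#' descends into the first child (in definition order) whose clause
#' conjunction it satisfies; when two sibling predicates hold for more
#' than 1\% of a node's events an overlap warning names the siblings.
#' Events matching no child at an internal node stay assigned to that node
#' ("ungated-at-level").  Frequencies are fractions of the pre-gated
#' events supplied.
#'
#' @param matrix a pre-gated, transformed \linkS4class{EventMatrix}.
#' @param tree a \linkS4class{GatingTree}.
#' @param cutoffs cutoff table on the same scale as \code{matrix} (use
#'   \code{\link{rescaleCutoffs}} after percentile normalization).
#' @param sampleId sample identifier stored in the result.
#' @return a \linkS4class{GatingResult}.
#' @export
applyGating <- function(matrix, tree, cutoffs = defaultCutoffs(),
                        sampleId = "sample1") {
  stopifnot(is(matrix, "EventMatrix"), is(tree, "GatingTree"))
  if (!matrix@scale %in% c("arcsinh", "arcsinh_p995"))
    stop("applyGating expects a transformed matrix", call. = FALSE)
  x <- matrix@exprs
  cols <- .antigenCols(matrix)
  n <- nrow(x)
  root <- names(tree@nodes)[vapply(tree@nodes, function(nd) is.na(nd$parent),
                                   logical(1))]
  assignment <- rep(root, n)
  counts <- setNames(integer(length(tree@nodes)), names(tree@nodes))
  counts[root] <- n

  recurse <- function(node, idx) {
    kids <- tree@nodes[[node]]$children
    if (!length(kids) || !length(idx)) return()
    hit <- matrix(FALSE, nrow = length(idx), ncol = length(kids))
    for (j in seq_along(kids))
      hit[, j] <- .evalClauses(tree@nodes[[kids[j]]]$clauses,
                               x[idx, , drop = FALSE], cols, cutoffs)
    if (length(kids) > 1L) {
      multi <- rowSums(hit) > 1L
      if (mean(multi) > 0.01) {
        worst <- which(hit[multi, , drop = FALSE][1, ])[1:2]
        warning(sprintf(
          "sibling gates '%s' and '%s' under '%s' overlap for %.1f%% of events",
          kids[worst[1]], kids[worst[2]], node, 100 * mean(multi)),
          call. = FALSE)
      }
    }
    first <- apply(hit, 1, function(r) {
      w <- which(r)
      if (length(w)) w[1] else NA_integer_
    })
    for (j in seq_along(kids)) {
      sub <- idx[!is.na(first) & first == j]
      if (!length(sub)) next
      assignment[sub] <<- kids[j]
      counts[kids[j]] <<- length(sub)
      recurse(kids[j], sub)
    }
  }
  recurse(root, seq_len(n))
  new("GatingResult", sampleId = sampleId, assignment = assignment,
      counts = counts, freq = counts / max(1L, n), nPregated = n,
      tree = tree)
}

#' Fraction of pre-gated events assigned to a leaf population
#'
#' @param result a \linkS4class{GatingResult}.
#' @return fraction in [0, 1].
#' @export
leafAssignedFraction <- function(result) {
  stopifnot(is(result, "GatingResult"))
  leaves <- names(result@tree@nodes)[vapply(result@tree@nodes, function(nd)
    length(nd$children) == 0L && !is.na(nd$parent), logical(1))]
  if (!length(leaves)) return(0)
  mean(result@assignment %in% leaves)
}

#' Leaf-population frequency vector of a gating result
#'
#' @param result a \linkS4class{GatingResult}.
#' @return named numeric of leaf frequencies (fractions of pre-gated).
#' @export
leafFrequencies <- function(result) {
  leaves <- names(result@tree@nodes)[vapply(result@tree@nodes, function(nd)
    length(nd$children) == 0L && !is.na(nd$parent), logical(1))]
  result@freq[leaves]
}

#' Combine gating results into a cohort count table
#'
#' @param results list of \linkS4class{GatingResult} objects sharing a
#'   gating tree.
#' @param metadata optional data.frame with a \code{sample_id} column to
#'   join as column metadata.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with
#'   populations as rows, samples as columns and assays \code{counts} and
#'   \code{freq} (fractions of pre-gated cells); \code{nPregated} is in
#'   the column data.
#' @export
frequencyTable <- function(results, metadata = NULL) {
  if (is(results, "GatingResult")) results <- list(results)
  ids <- vapply(results, function(r) r@sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1], call. = FALSE)
  prof <- unique(vapply(results, function(r) r@tree@profile, character(1)))
  if (length(prof) != 1L)
    stop("all gating results must share a tree", call. = FALSE)
  pops <- names(results[[1]]@tree@nodes)
  counts <- vapply(results, function(r) r@counts[pops], integer(length(pops)))
  freq <- vapply(results, function(r) r@freq[pops], numeric(length(pops)))
  counts <- matrix(counts, nrow = length(pops),
                   dimnames = list(pops, ids))
  freq <- matrix(freq, nrow = length(pops), dimnames = list(pops, ids))
  cd <- S4Vectors::DataFrame(
    sample_id = ids,
    nPregated = vapply(results, function(r) r@nPregated, integer(1)),
    row.names = ids)
  if (!is.null(metadata)) {
    m <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    for (nm in setdiff(names(m), "sample_id")) cd[[nm]] <- m[[nm]]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, freq = freq), colData = cd,
    metadata = list(profile = prof))
}
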