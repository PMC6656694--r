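# Self-organizing-map clustering, metaclustering, automatic lineage
# annotation, and within-lineage subclustering.

# squared Euclidean distances events x nodes
.dist2 <- function(x, w) {
  d <- outer(rowSums(x^2), rowSums(w^2), "+") - 2 * x %*% t(w)
  d[d < 0] <- 0
  d
}

#' Train a batch self-organizing map
#'
#' Standard batch SOM on a rectangular grid: the codebook is initialized
#' from a quantile grid of the data along its first principal axis
#' (deterministic given the seed), then per epoch every event is assigned
#' to its nearest codebook vector (Euclidean distance over the selected
#' channels) and each node is updated as the neighborhood-weighted mean of
#' its events, with a Gaussian neighborhood whose radius shrinks linearly
#' between \code{radius[1]} and \code{radius[2]}.
#'
#' @param matrix an \linkS4class{EventMatrix} with
#'   \code{scale = "arcsinh_p995"}.
#' @param grid integer (rows, cols); default 10 x 10.
#' @param epochs training epochs; default 10.
#' @param seed integer seed.
#' @param channels antigens used for clustering; default: all panel
#'   antigens of category lineage or subset present in the matrix
#'   (activation and checkpoint channels are summarized post hoc, not
#'   clustered).
#' @param radius initial and final neighborhood radius; default
#'   \code{c(max(grid)/2, 0.5)}.
#' @return a \linkS4class{SOMModel} (with the per-event best-matching node
#'   in its \code{mapping} slot).
#' @export
trainSOM <- function(matrix, grid = c(10L, 10L), epochs = 10L, seed = 1L,
                     channels = NULL, radius = NULL) {
  stopifnot(is(matrix, "EventMatrix"))
  if (matrix@scale != "arcsinh_p995")
    stop("trainSOM expects a percentile-normalized matrix", call. = FALSE)
  grid <- as.integer(grid)
  nNodes <- prod(grid)
  if (nEvents(matrix) < nNodes * 10L)
    stop("too few events for a ", grid[1], "x", grid[2], " grid (need >= ",
         nNodes * 10L, ")", call. = FALSE)
  if (is.null(channels)) channels <- .clusterChannels(matrix)
  cols <- .antigenCols(matrix)
  miss <- setdiff(channels, names(cols))
  if (length(miss))
    stop("channels not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- matrix@exprs[, cols[channels], drop = FALSE]
  colnames(x) <- channels
  if (is.null(radius)) radius <- c(max(grid) / 2, 0)

  set.seed(seed)
  # init: order events along the dominant principal axis, place nodes at
  # quantile positions (jittered means of small quantile bins)
  ctr <- sweep(x, 2, colMeans(x))
  v <- svd(ctr[sample.int(nrow(x), min(nrow(x), 2000L)), , drop = FALSE],
           nu = 0, nv = 1)$v[, 1]
  sc <- as.numeric(ctr %*% v)
  qs <- quantile(sc, probs = seq(0, 1, length.out = nNodes + 1L),
                 names = FALSE)
  bin <- findInterval(sc, qs[-c(1, nNodes + 1L)]) + 1L
  w <- matrix(0, nNodes, ncol(x), dimnames = list(NULL, channels))
  for (j in seq_len(nNodes)) {
    rows <- which(bin == j)
    if (!length(rows)) rows <- sample.int(nrow(x), 10L)
    w[j, ] <- colMeans(x[rows, , drop = FALSE])
  }

  # grid coordinates and node-node distances for the neighborhood kernel
  gr <- expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2]))
  gd2 <- as.matrix(dist(gr))^2
  bmu <- integer(nrow(x))
  for (e in seq_len(epochs)) {
    # radius reaches its floor three epochs before the end, leaving pure
    # quantization epochs for the codebook to settle
    r <- radius[1] + (radius[2] - radius[1]) *
      min(1, (e - 1) / max(1L, epochs - 4L))
    d2 <- .dist2(x, w)
    bmu <- max.col(-d2, ties.method = "first")
    # vanishing radius: pure vector-quantization (k-means) update
    vq <- r < 0.05
    h <- if (vq) diag(nNodes) else exp(-gd2 / (2 * r^2))
    cnt <- tabulate(bmu, nNodes)
    sums <- rowsum(x, group = bmu, reorder = FALSE)
    full <- matrix(0, nNodes, ncol(x))
    full[as.integer(rownames(sums)), ] <- sums
    num <- h %*% full
    den <- as.numeric(h %*% cnt)
    upd <- den > 0
    w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    if (vq && any(cnt == 0L)) {
      # standard empty-cluster handling: re-seed unused nodes at the
      # events farthest from their current centroid, so small isolated
      # populations are guaranteed representation
      dmin <- d2[cbind(seq_len(nrow(x)), bmu)]
      far <- order(dmin, decreasing = TRUE)[seq_len(sum(cnt == 0L))]
      w[cnt == 0L, ] <- x[far, , drop = FALSE]
    }
  }
  bmu <- max.col(-.dist2(x, w), ties.method = "first")
  new("SOMModel", grid = grid, codebook = w, channels = channels,
      mapping = bmu, seed = as.integer(seed), epochs = as.integer(epochs),
      radius = as.numeric(radius))
}

# default clustering channels: lineage + subset categories
.clusterChannels <- function(matrix, panel = referencePanel()) {
  ch <- panel@channels
  keep <- ch$antigen[ch$category %in% c("lineage", "subset") &
                     !ch$category %in% "exclusion"]
  intersect(keep, names(.antigenCols(matrix)))
}

#' Metacluster SOM nodes
#'
#' Average-linkage hierarchical clustering of the codebook vectors
#' (Euclidean distance), cut at \code{k} metaclusters.  Singleton
#' metaclusters are permitted.
#'
#' @param model a \linkS4class{SOMModel}.
#' @param k number of metaclusters (1 <= k <= number of nodes).
#' @return integer metacluster id per SOM node.
#' @export
metacluster <- function(model, k) {
  stopifnot(is(model, "SOMModel"))
  nNodes <- nrow(model@codebook)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nNodes)
    stop("k must lie in [1, ", nNodes, "]", call. = FALSE)
  hc <- hclust(dist(model@codebook), method = "average")
  cutree(hc, k = as.integer(k))
}

# score one definition against a median profile: fraction of matched
# sign clauses (clause matches when the median is on the required side)
.scoreDefinition <- function(clauses, profile, cutoffs) {
  if (!nrow(clauses)) return(1)
  ok <- vapply(seq_len(nrow(clauses)), function(i) {
    a <- clauses$antigen[i]
    v <- profile[[a]]
    switch(clauses$relation[i],
      gte_pos  = v >= .cutoffFor(cutoffs, a),
      lt_pos   = v < .cutoffFor(cutoffs, a),
      gte_high = v >= .cutoffFor(cutoffs, a, secondary = TRUE),
      lte_low  = v <= .cutoffFor(cutoffs, a, secondary = TRUE))
  }, logical(1))
  mean(ok)
}

#' Annotate metaclusters with lineage labels
#'
#' Per metacluster, the median expression profile (over its events) is
#' scored against every population definition: the score is the fraction
#' of the definition's sign clauses whose side of the relevant cutoff the
#' metacluster median lies on.  The metacluster receives the deepest
#' definition for which the definition itself and every ancestor attain a
#' score of at least \code{scoreFloor}; ties are broken by the more
#' specific (deeper) definition, then the larger score, then the
#' lexicographically smaller name.  A metacluster for which even the root
#' fails the floor is \code{"Unassigned"}.
#'
#' @param matrix the \linkS4class{EventMatrix} the model was trained on.
#' @param model a \linkS4class{SOMModel}.
#' @param meta integer metacluster map from \code{\link{metacluster}}.
#' @param lineages a \linkS4class{LineageTable} (or a subtree of one).
#' @param cutoffs cutoff table on the matrix scale.
#' @param scoreFloor minimum clause-match fraction; default 0.9.
#' @return a \linkS4class{ClusterLabeling}.
#' @export
annotateClusters <- function(matrix, model, meta, lineages,
                             cutoffs, scoreFloor = 0.9) {
  stopifnot(is(matrix, "EventMatrix"), is(model, "SOMModel"))
  tree <- gatingTree(lineages)
  idx <- .lineageIndex(lineages)
  cols <- .antigenCols(matrix)
  ks <- sort(unique(meta))
  evMeta <- meta[model@mapping]
  prof <- matrix(NA_real_, nrow = length(ks), ncol = length(cols),
                 dimnames = list(ks, names(cols)))
  empty <- logical(length(ks))
  for (i in seq_along(ks)) {
    rows <- which(evMeta == ks[i])
    empty[i] <- length(rows) == 0L   # metacluster of event-less nodes
    if (!empty[i])
      prof[i, ] <- apply(matrix@exprs[rows, cols, drop = FALSE], 2, median)
  }
  defs <- names(tree@nodes)
  depth <- idx$depth[defs]
  labels <- character(length(ks))
  scores <- numeric(length(ks))
  for (i in seq_along(ks)) {
    if (empty[i]) { labels[i] <- "Unassigned"; next }
    p <- setNames(prof[i, ], colnames(prof))
    sc <- vapply(defs, function(nm)
      .scoreDefinition(tree@nodes[[nm]]$clauses, p, cutoffs), numeric(1))
    eligible <- vapply(defs, function(nm) {
      anc <- c(nm, .ancestors(nm, idx$parent))
      all(sc[anc] >= scoreFloor)
    }, logical(1))
    if (!any(eligible)) {
      labels[i] <- "Unassigned"; scores[i] <- max(sc)
    } else {
      # deepest definition first; ties broken by the more specific
      # definition (more sign clauses), then the larger score, then name
      cand <- defs[eligible]
      ncl <- vapply(cand, function(nm) nrow(tree@nodes[[nm]]$clauses),
                    integer(1))
      o <- order(-depth[cand], -ncl, -sc[cand], cand)
      labels[i] <- cand[o[1]]
      scores[i] <- sc[cand[o[1]]]
    }
  }
  nodeMeta <- as.integer(match(meta, ks))
  new("ClusterLabeling", nodeMeta = nodeMeta,
      metaLabel = labels, metaProfile = prof, score = scores)
}

#' Per-event labels implied by a cluster labeling
#'
#' @param model a \linkS4class{SOMModel}.
#' @param labeling a \linkS4class{ClusterLabeling}.
#' @return character label per event.
#' @export
eventLabels <- function(model, labeling) {
  labeling@metaLabel[labeling@nodeMeta[model@mapping]]
}

#' Subcluster one lineage into its child subsets
#'
#' Re-runs SOM + metaclustering + annotation restricted to the events of
#' one lineage, scoring only against that lineage's subtree, and returns
#' the refined per-event labels (other events keep their labels; locality).
#'
#' @param matrix the full \linkS4class{EventMatrix}.
#' @param labels current per-event labels.
#' @param lineage name of the population to refine.
#' @param lineages the full \linkS4class{LineageTable}.
#' @param cutoffs cutoff table on the matrix scale.
#' @param grid SOM grid for the subclustering; default (\code{NULL}):
#'   adaptive, about one node per 15 events, between 2 x 2 and 10 x 10.
#' @param k metaclusters; default (\code{NULL}): one per node (identity
#'   metaclustering, i.e. node-resolution annotation, which lets rare
#'   subsets claim their own node).
#' @param seed integer seed.
#' @param minEvents minimum events required (default 200); below it a
#'   warning is raised and labels are returned unchanged.
#' @param scoreFloor annotation floor.
#' @return character vector of refined per-event labels.
#' @export
subcluster <- function(matrix, labels, lineage, lineages, cutoffs,
                       grid = NULL, k = NULL, seed = 1L,
                       minEvents = 200L, scoreFloor = 0.9) {
  d <- lineages@definitions
  if (!lineage %in% d$name)
    stop("unknown lineage '", lineage, "'", call. = FALSE)
  idx <- .lineageIndex(lineages)
  inSubtree <- vapply(d$name, function(nm)
    nm == lineage || lineage %in% .ancestors(nm, idx$parent), logical(1))
  rows <- which(labels %in% d$name[inSubtree])
  if (is.null(grid)) {
    side <- floor(sqrt(min(196, max(4, length(rows) %/% 15L))))
    side <- max(2L, min(side, floor(sqrt(length(rows) / 10))))
    grid <- c(side, side)
  }
  if (length(rows) < max(minEvents, prod(grid) * 10L)) {
    warning("lineage '", lineage, "' has too few events (", length(rows),
            ") for subclustering; labels unchanged", call. = FALSE)
    return(labels)
  }
  sub <- matrix[rows]
  subTable <- .subtreeTable(lineages, lineage)
  # cluster on the antigens that discriminate the subtree's definitions
  # (the lineage-defining markers are constant within the lineage and
  # would only add noise to the quantization)
  dd <- subTable@definitions
  chans <- unique(unlist(c(lapply(dd$positive, names),
                           lapply(dd$negative, names))))
  chans <- intersect(chans, names(.antigenCols(sub)))
  if (length(chans) < 1L) chans <- NULL
  model <- trainSOM(sub, grid = grid, seed = seed, channels = chans)
  if (is.null(k)) k <- nrow(model@codebook)
  k <- min(k, nrow(model@codebook))
  meta <- metacluster(model, k)
  lab <- annotateClusters(sub, model, meta, subTable, cutoffs,
                          scoreFloor = scoreFloor)
  refined <- eventLabels(model, lab)
  # events left at the subtree root keep the lineage label; events whose
  # node fails even the lineage's own clauses are expelled as Unassigned
  refined[refined == "CD45+ leukocytes"] <- lineage
  out <- labels
  out[rows] <- refined
  out
}

# extract the subtree under `lineage` as a standalone LineageTable whose
# root is relabeled "CD45+ leukocytes" internally for validity, keeping
# original names for all other nodes; the root accumulates the full clause
# path from the original root so mis-pooled events fail annotation and
# are expelled
.subtreeTable <- function(lineages, lineage) {
  d <- lineages@definitions
  idx <- .lineageIndex(lineages)
  keep <- vapply(d$name, function(nm)
    nm == lineage || lineage %in% .ancestors(nm, idx$parent), logical(1))
  sub <- d[keep, , drop = FALSE]
  if (lineage != "CD45+ leukocytes") {
    # accumulate (antigen -> level, sign) along the path; a clause deeper
    # in the path overrides an earlier one for the same antigen
    path <- rev(c(lineage, .ancestors(lineage, idx$parent)))
    lev <- character(0); sign <- character(0)
    for (nm in path) {
      i <- match(nm, d$name)
      p <- d$positive[[i]]; ng <- d$negative[[i]]
      lev[names(p)] <- p;  sign[names(p)] <- "pos"
      lev[names(ng)] <- ng; sign[names(ng)] <- "neg"
    }
    ri <- match(lineage, sub$name)
    sub$parent[ri] <- NA_character_
    sub$positive[[ri]] <- lev[sign == "pos"]
    sub$negative[[ri]] <- lev[sign == "neg"]
    sub$name[ri] <- "CD45+ leukocytes"
    sub$parent[!is.na(sub$parent) & sub$parent == lineage] <-
      "CD45+ leukocytes"
  }
  rownames(sub) <- NULL
  new("LineageTable", profile = paste0(lineages@profile, ":", lineage),
      definitions = sub)
}
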