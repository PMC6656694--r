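#' @import methods
#' @importFrom stats approx coef cor cutree dist fitted hclust
#'   lm median na.omit p.adjust pnorm pt quantile rbinom rmultinom rnorm
#'   runif sd setNames density glm poisson offset vcov
#' @importFrom utils head read.delim write.table packageVersion
NULL

# -- scale levels used throughout: raw ion counts, arcsinh(x/cofactor), and
#    arcsinh divided by a per-channel upper percentile
.SCALES <- c("raw", "arcsinh", "arcsinh_p995")

#' Per-event intensity matrix with channel metadata
#'
#' The central event-level container: an events x channels matrix of
#' non-negative intensities (raw dual counts, or transformed values flagged
#' by the \code{scale} slot), per-channel metadata mirroring the FCS
#' \code{$PnN}/\code{$PnS} keywords plus the metal and antigen assignment,
#' and a per-event acquisition time vector (monotone non-decreasing).
#'
#' @slot exprs numeric matrix, events x channels; column names are the FCS
#'   short channel names.
#' @slot channelMeta data.frame with one row per column of \code{exprs}:
#'   \code{name} ($PnN), \code{desc} ($PnS), \code{metal}, \code{antigen}
#'   (NA for non-antibody channels) and \code{class} (one of
#'   \code{"antibody"}, \code{"dna"}, \code{"viability"}, \code{"bead"},
#'   \code{"barcode"}, \code{"length"}, \code{"time"}).
#' @slot time numeric per-event acquisition time, sorted ascending.
#' @slot scale character flag, one of \code{"raw"}, \code{"arcsinh"},
#'   \code{"arcsinh_p995"}; transform operations only ever move it forward
#'   along that chain.
#' @slot scaleFactors named numeric; after percentile normalization, the
#'   per-channel divisors that were applied (empty before).
#'
#' @export
setClass("EventMatrix",
  slots = c(
    exprs        = "matrix",
    channelMeta  = "data.frame",
    time         = "numeric",
    scale        = "character",
    scaleFactors = "numeric"
  ),
  prototype = prototype(scale = "raw", scaleFactors = numeric(0))
)

setValidity("EventMatrix", function(object) {
  msg <- character(0)
  if (!is.numeric(object@exprs))
    msg <- c(msg, "exprs must be numeric")
  if (any(!is.finite(object@exprs)))
    msg <- c(msg, "exprs contains non-finite values")
  if (nrow(object@channelMeta) != ncol(object@exprs))
    msg <- c(msg, "channelMeta rows must match exprs columns")
  need <- c("name", "desc", "metal", "antigen", "class")
  if (!all(need %in% names(object@channelMeta)))
    msg <- c(msg, paste("channelMeta must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@time) != nrow(object@exprs))
    msg <- c(msg, "time length must equal event count")
  if (is.unsorted(object@time))
    msg <- c(msg, "time must be non-decreasing")
  if (!object@scale %in% .SCALES)
    msg <- c(msg, paste("scale must be one of", paste(.SCALES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Antibody panel definition
#'
#' An ordered set of antibody-channel records (metal isotope tag, target
#' antigen, clone, category, cellular compartment) plus the auxiliary
#' non-antibody channels (DNA intercalators, viability, event length,
#' calibration-bead and barcode channels) that together define the assay.
#'
#' @slot name panel name.
#' @slot channels data.frame of antibody channels: \code{metal},
#'   \code{antigen}, \code{clone}, \code{category} (lineage, subset,
#'   activation, checkpoint, exclusion) and \code{compartment} (surface,
#'   intracellular).
#' @slot auxiliary data.frame of non-antibody channels: \code{metal}
#'   (NA for Time / Event_length), \code{name}, \code{role}.
#'
#' @export
setClass("AntibodyPanel",
  slots = c(name = "character", channels = "data.frame",
            auxiliary = "data.frame"))

setValidity("AntibodyPanel", function(object) {
  msg <- character(0)
  ch <- object@channels
  need <- c("metal", "antigen", "clone", "category", "compartment")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$metal))
    msg <- c(msg, "duplicated metal label among antibody channels")
  if (anyDuplicated(ch$antigen))
    msg <- c(msg, "duplicated antigen among antibody channels")
  if (any(!ch$category %in%
          c("lineage", "subset", "activation", "checkpoint", "exclusion")))
    msg <- c(msg, "invalid category value")
  if (any(!ch$compartment %in% c("surface", "intracellular")))
    msg <- c(msg, "invalid compartment value")
  aux <- object@auxiliary
  if (any(stats::na.omit(aux$metal) %in% ch$metal))
    msg <- c(msg, "auxiliary channels must be metal-disjoint from antibody channels")
  if (length(msg)) msg else TRUE
})

#' Lineage/subset marker-sign definition table
#'
#' A tree of population definitions rooted at "CD45+ leukocytes".  Each
#' definition lists the marker signs that distinguish the population from
#' its siblings: \code{positive} clauses at level \code{pos} (above the
#' primary cutoff) or \code{high} (above the secondary cutoff), and
#' \code{negative} clauses at level \code{neg} (below primary) or
#' \code{low} (below secondary).  Clauses are incremental with respect to
#' the parent; sibling order encodes gating priority.
#'
#' @slot profile profile name the table was loaded from.
#' @slot definitions data.frame with columns \code{name}, \code{parent}
#'   and list-columns \code{positive}, \code{negative} (named character
#'   vectors antigen -> level) and \code{ignored}.
#'
#' @export
setClass("LineageTable",
  slots = c(profile = "character", definitions = "data.frame"))

setValidity("LineageTable", function(object) {
  d <- object@definitions
  msg <- character(0)
  if (!all(c("name", "parent", "positive", "negative", "ignored") %in% names(d)))
    return("definitions must have name/parent/positive/negative/ignored columns")
  if (anyDuplicated(d$name))
    msg <- c(msg, "duplicated population names")
  root <- d$name[is.na(d$parent)]
  if (length(root) != 1L || root != "CD45+ leukocytes")
    msg <- c(msg, "definitions must form a tree rooted at 'CD45+ leukocytes'")
  orphan <- setdiff(stats::na.omit(d$parent), d$name)
  if (length(orphan))
    msg <- c(msg, paste("unknown parent:", paste(orphan, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Hierarchical gating tree
#'
#' A validated, executable form of a \linkS4class{LineageTable}: every node
#' carries the conjunction of threshold clauses (antigen, relation) that an
#' event must satisfy, relative to its parent.  Relations are
#' \code{gte_pos} / \code{lt_pos} against the primary (positive/negative)
#' cutoff and \code{gte_high} / \code{lte_low} against the secondary
#' (low/high) cutoff.
#'
#' @slot profile profile name.
#' @slot nodes named list; each element has \code{name}, \code{parent},
#'   \code{children} (in priority order) and \code{clauses} (data.frame
#'   antigen/relation).
#'
#' @export
setClass("GatingTree", slots = c(profile = "character", nodes = "list"))

#' Result of hierarchical gating for one sample
#'
#' @slot sampleId sample identifier.
#' @slot assignment character per pre-gated event: the deepest tree node
#'   reached (leaf name, or an internal node name for events
#'   "ungated-at-level").
#' @slot counts named integer per tree node (events at or below the node).
#' @slot freq named numeric, node count / pre-gated count.
#' @slot nPregated number of pre-gated events gated.
#' @slot tree the \linkS4class{GatingTree} used.
#'
#' @export
setClass("GatingResult",
  slots = c(sampleId = "character", assignment = "character",
            counts = "integer", freq = "numeric", nPregated = "integer",
            tree = "GatingTree"))

#' Trained self-organizing map
#'
#' Batch-trained SOM codebook over a rectangular grid.  Training is
#' deterministic given the seed: nodes are initialized from a quantile grid
#' of the data and updated per epoch as neighborhood-weighted means with a
#' linearly shrinking Gaussian radius.
#'
#' @slot grid integer (rows, cols).
#' @slot codebook nodes x channels matrix on the transformed scale.
#' @slot channels antigens used for training.
#' @slot mapping integer best-matching node per training event.
#' @slot seed,epochs,radius training parameters (radius = initial/final).
#'
#' @export
setClass("SOMModel",
  slots = c(grid = "integer", codebook = "matrix", channels = "character",
            mapping = "integer", seed = "integer", epochs = "integer",
            radius = "numeric"))

#' Cluster-to-lineage annotation
#'
#' @slot nodeMeta integer metacluster id per SOM node.
#' @slot metaLabel character label per metacluster (a lineage-table name or
#'   "Unassigned").
#' @slot metaProfile metacluster x antigen matrix of median expression.
#' @slot score numeric per metacluster: fraction of matched sign clauses of
#'   the assigned definition.
#'
#' @export
setClass("ClusterLabeling",
  slots = c(nodeMeta = "integer", metaLabel = "character",
            metaProfile = "matrix", score = "numeric"))
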