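#' @rdname EventMatrix-class
#' @param object,x an \linkS4class{EventMatrix}
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname EventMatrix-class
#' @export
setGeneric("channelMeta", function(object) standardGeneric("channelMeta"))

#' @rdname EventMatrix-class
#' @export
setGeneric("acqTime", function(object) standardGeneric("acqTime"))

#' @rdname EventMatrix-class
#' @export
setGeneric("transformScale", function(object) standardGeneric("transformScale"))

#' @rdname EventMatrix-class
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname EventMatrix-class
#' @export
setMethod("exprs", "EventMatrix", function(object) object@exprs)

#' @rdname EventMatrix-class
#' @export
setMethod("channelMeta", "EventMatrix", function(object) object@channelMeta)

#' @rdname EventMatrix-class
#' @export
setMethod("acqTime", "EventMatrix", function(object) object@time)

#' @rdname EventMatrix-class
#' @export
setMethod("transformScale", "EventMatrix", function(object) object@scale)

#' @rdname EventMatrix-class
#' @export
setMethod("nEvents", "EventMatrix", function(object) nrow(object@exprs))

#' @rdname EventMatrix-class
#' @export
setMethod("dim", "EventMatrix", function(x) dim(x@exprs))

#' Subset an EventMatrix by events
#'
#' @param x an \linkS4class{EventMatrix}
#' @param i logical or integer event index
#' @param j unused (channels are fixed by the panel)
#' @param ... ignored
#' @param drop ignored
#' @return an \linkS4class{EventMatrix} with the selected events
#' @export
setMethod("[", "EventMatrix", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) stop("channel subsetting is not supported; subset events only")
  new("EventMatrix", exprs = x@exprs[i, , drop = FALSE],
      channelMeta = x@channelMeta, time = x@time[i],
      scale = x@scale, scaleFactors = x@scaleFactors)
})

setMethod("show", "EventMatrix", function(object) {
  cat(sprintf("EventMatrix: %d events x %d channels [scale: %s]\n",
              nrow(object@exprs), ncol(object@exprs), object@scale))
  cls <- table(object@channelMeta$class)
  cat("  channels:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  if (length(object@time))
    cat(sprintf("  time: [%.3g, %.3g]\n", min(object@time), max(object@time)))
})

#' @rdname AntibodyPanel-class
#' @param object an \linkS4class{AntibodyPanel}
#' @export
setGeneric("panelChannels", function(object) standardGeneric("panelChannels"))

#' @rdname AntibodyPanel-class
#' @export
setGeneric("auxiliaryChannels",
           function(object) standardGeneric("auxiliaryChannels"))

#' @rdname AntibodyPanel-class
#' @export
setGeneric("panelAntigens", function(object) standardGeneric("panelAntigens"))

#' @rdname AntibodyPanel-class
#' @export
setMethod("panelChannels", "AntibodyPanel", function(object) object@channels)

#' @rdname AntibodyPanel-class
#' @export
setMethod("auxiliaryChannels", "AntibodyPanel",
          function(object) object@auxiliary)

#' @rdname AntibodyPanel-class
#' @export
setMethod("panelAntigens", "AntibodyPanel",
          function(object) object@channels$antigen)

setMethod("show", "AntibodyPanel", function(object) {
  cat(sprintf("AntibodyPanel '%s': %d antibody channels, %d auxiliary\n",
              object@name, nrow(object@channels), nrow(object@auxiliary)))
  cat("  categories:",
      paste(sprintf("%s=%d", names(table(object@channels$category)),
                    table(object@channels$category)), collapse = ", "), "\n")
})

#' @rdname LineageTable-class
#' @param object a \linkS4class{LineageTable}
#' @export
setGeneric("lineageNames", function(object) standardGeneric("lineageNames"))

#' @rdname LineageTable-class
#' @export
setGeneric("lineageLeaves", function(object) standardGeneric("lineageLeaves"))

#' @rdname LineageTable-class
#' @export
setMethod("lineageNames", "LineageTable",
          function(object) object@definitions$name)

#' @rdname LineageTable-class
#' @export
setMethod("lineageLeaves", "LineageTable", function(object) {
  d <- object@definitions
  setdiff(d$name, stats::na.omit(d$parent))
})

setMethod("show", "LineageTable", function(object) {
  d <- object@definitions
  cat(sprintf("LineageTable '%s': %d populations (%d leaves)\n",
              object@profile, nrow(d), length(lineageLeaves(object))))
})

setMethod("show", "GatingTree", function(object) {
  cat(sprintf("GatingTree '%s': %d nodes\n", object@profile,
              length(object@nodes)))
})

setMethod("show", "GatingResult", function(object) {
  cat(sprintf("GatingResult '%s': %d pre-gated events, %.1f%% assigned to leaves\n",
              object@sampleId, object@nPregated,
              100 * leafAssignedFraction(object)))
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %dx%d grid, %d channels, %d mapped events (seed %d)\n",
              object@grid[1], object@grid[2], length(object@channels),
              length(object@mapping), object@seed))
})

setMethod("show", "ClusterLabeling", function(object) {
  lab <- table(object@metaLabel)
  cat(sprintf("ClusterLabeling: %d metaclusters, %d labels (%d Unassigned)\n",
              length(object@metaLabel), length(unique(object@metaLabel)),
              sum(object@metaLabel == "Unassigned")))
})
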