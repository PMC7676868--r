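#' @title Accessors for tracking objects
#' @description Small accessor layer so downstream code never touches slots.
#' @param object a \linkS4class{TrackletGraph}, \linkS4class{ArenaSimulation}
#'   or \linkS4class{IDSolution}.
#' @return `trackletNodes`/`trackletEdges` return data.frames;
#'   `trackletBlobs` a list of per-tracklet blob tables; `nTracklets` and
#'   `nFrames` integers; `groundTruth` the per-frame truth table;
#'   `assignedIDs`/`possibleIDs` logical tracklets-x-IDs matrices;
#'   `idLabels` a character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackletNodes", function(object) standardGeneric("trackletNodes"))
#' @rdname accessors
#' @export
setGeneric("trackletEdges", function(object) standardGeneric("trackletEdges"))
#' @rdname accessors
#' @export
setGeneric("trackletBlobs", function(object) standardGeneric("trackletBlobs"))
#' @rdname accessors
#' @export
setGeneric("nTracklets", function(object) standardGeneric("nTracklets"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("agentTable", function(object) standardGeneric("agentTable"))
#' @rdname accessors
#' @export
setGeneric("assignedIDs", function(object) standardGeneric("assignedIDs"))
#' @rdname accessors
#' @export
setGeneric("possibleIDs", function(object) standardGeneric("possibleIDs"))
#' @rdname accessors
#' @export
setGeneric("idLabels", function(object) standardGeneric("idLabels"))

#' @rdname accessors
setMethod("trackletNodes", "TrackletGraph", function(object) object@nodes)
#' @rdname accessors
setMethod("trackletEdges", "TrackletGraph", function(object) object@edges)
#' @rdname accessors
setMethod("trackletBlobs", "TrackletGraph", function(object) object@blobs)
#' @rdname accessors
setMethod("nTracklets", "TrackletGraph", function(object) nrow(object@nodes))
#' @rdname accessors
setMethod("nFrames", "TrackletGraph", function(object) object@nFrames)
#' @rdname accessors
setMethod("nFrames", "ArenaSimulation", function(object) object@nFrames)
#' @rdname accessors
setMethod("groundTruth", "ArenaSimulation", function(object) object@gt)
#' @rdname accessors
setMethod("agentTable", "ArenaSimulation", function(object) object@agents)
#' @rdname accessors
setMethod("assignedIDs", "IDSolution", function(object) object@assigned)
#' @rdname accessors
setMethod("possibleIDs", "IDSolution", function(object) object@possible)
#' @rdname accessors
setMethod("idLabels", "IDSolution", function(object) object@ids)

setMethod("show", "ArenaSimulation", function(object) {
  cat(sprintf("ArenaSimulation: %d agents, %d frames, %dx%d px arena (%s boundary)\n",
              nrow(object@agents), object@nFrames,
              object@arena$width, object@arena$height,
              if (object@arena$openBoundary) "open" else "closed"))
  agg <- object@gt$aggregate
  multi <- tapply(agg, object@gt$frame, function(a) any(duplicated(a[!is.na(a)])))
  cat(sprintf("  frames with aggregates: %d\n", sum(multi)))
})

setMethod("show", "TrackletGraph", function(object) {
  nd <- object@nodes
  cat(sprintf("TrackletGraph: %d tracklets, %d edges over %d frames (%dx%d px)\n",
              nrow(nd), nrow(object@edges), object@nFrames,
              object@frameDim[2L], object@frameDim[1L]))
  if (nrow(nd))
    cat(sprintf("  kinds: %s; labeled: %d\n",
                paste(sprintf("%s=%d", names(table(nd$kind)), table(nd$kind)),
                      collapse = " "),
                sum(!is.na(nd$label))))
})

setMethod("show", "IDSolution", function(object) {
  cat(sprintf("IDSolution: %d tracklets x %d IDs; %d assignments (%d classifier, %d propagated), %d contradicted seeds\n",
              nrow(object@assigned), length(object@ids), sum(object@assigned),
              sum(object@provenance == "classifier", na.rm = TRUE),
              sum(object@provenance == "propagated", na.rm = TRUE),
              nrow(object@contradicted)))
})
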