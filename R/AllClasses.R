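#' Class "ArenaSimulation": synthetic colony with full ground truth
#'
#' Container returned by [simulateColony()]. Holds the agent roster, the
#' arena geometry, the motion parameters, and the per-frame ground truth
#' (centroid, heading, presence, aggregate membership) for every agent.
#' Frames are not stored: they are rendered on demand by [renderFrame()] /
#' [frameSource()] so that long simulations need not fit in memory.
#'
#' @slot agents data.frame with one row per agent: \code{id}, \code{nTags},
#'   \code{tagColors} (list column of RGB triples), \code{bodyLength},
#'   \code{bodyWidth}, \code{speed}.
#' @slot arena list: \code{width}, \code{height}, \code{roiMask}
#'   (height x width logical), \code{openBoundary}.
#' @slot gt data.frame: \code{frame}, \code{id}, \code{x}, \code{y},
#'   \code{heading}, \code{present}, \code{aggregate}, \code{drawOrder}.
#' @slot nFrames integer number of simulated frames.
#' @slot motion list of motion-model parameters (see [simulateColony()]).
#' @slot seed integer master seed of the simulation.
#'
#' @seealso [simulateColony()], [renderFrames()], [writeFixture()]
#' @export
setClass("ArenaSimulation",
  representation(agents = "data.frame", arena = "list", gt = "data.frame",
                 nFrames = "integer", motion = "list", seed = "integer"))

setValidity("ArenaSimulation", function(object) {
  msg <- character()
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (anyDuplicated(object@agents$id))
    msg <- c(msg, "agent id labels must be unique")
  nt <- lengths(object@agents$tagColors)
  if (any(nt < 1L | nt > 3L))
    msg <- c(msg, "each agent must carry 1 to 3 tags")
  if (!all(dim(object@arena$roiMask) ==
           c(object@arena$height, object@arena$width)))
    msg <- c(msg, "roiMask dimensions must equal frame dimensions")
  if (!object@arena$openBoundary && !all(object@gt$present))
    msg <- c(msg, "presence flag may be FALSE only with an open boundary")
  if (length(msg)) msg else TRUE
})

#' Class "TrackletGraph": directed acyclic graph of tracklets
#'
#' The central tracking data structure. Nodes are tracklets (maximal runs of
#' exclusively linked blobs in consecutive frames sharing one animal
#' composition); a directed edge records animal flow from a tracklet closing
#' at frame t - 1 into one opening at frame t (merge/split events).
#'
#' @slot nodes data.frame with one row per tracklet: \code{tracklet},
#'   \code{start}, \code{end}, \code{nBlobs}, \code{kind} ("single",
#'   "multi" or "unknown"), \code{label} (ID string or NA),
#'   \code{confidence}, \code{startsOpen}, \code{endsOpen} (boundary flags).
#' @slot edges data.frame with columns \code{from}, \code{to} (tracklet ids).
#' @slot blobs list, one element per tracklet: data.frame \code{frame},
#'   \code{x}, \code{y}, \code{area}, \code{orient} plus list columns
#'   \code{mask} (linear pixel indices) and \code{crop} (RGB array or NULL).
#' @slot nFrames integer; frames are 1..nFrames.
#' @slot frameDim integer c(height, width) of the source frames.
#'
#' @seealso [buildTrackletGraph()], [solveGraph()]
#' @export
setClass("TrackletGraph",
  representation(nodes = "data.frame", edges = "data.frame", blobs = "list",
                 nFrames = "integer", frameDim = "integer"))

setValidity("TrackletGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character()
  if (nrow(nd) && !identical(nd$tracklet, seq_len(nrow(nd))))
    msg <- c(msg, "tracklet ids must be 1..n in order of opening")
  if (any(nd$start > nd$end)) msg <- c(msg, "start must be <= end")
  if (length(object@blobs) != nrow(nd))
    msg <- c(msg, "one blob table per tracklet required")
  if (nrow(ed)) {
    if (any(ed$from < 1L | ed$to > nrow(nd)))
      msg <- c(msg, "edge endpoints out of range")
    if (any(nd$end[ed$from] + 1L != nd$start[ed$to]))
      msg <- c(msg, "edges must connect a tracklet ending at t-1 to one starting at t")
    g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                       vertices = data.frame(name = nd$tracklet))
    if (!igraph::is_dag(g)) msg <- c(msg, "tracklet graph must be acyclic")
  }
  for (i in seq_along(object@blobs)) {
    b <- object@blobs[[i]]
    if (!identical(b$frame, seq.int(nd$start[i], nd$end[i]))) {
      msg <- c(msg, sprintf("tracklet %d blobs must span frames start..end, one per frame", i))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Class "IDSolution": state of the ID propagation solver
#'
#' Per-tracklet bookkeeping of the greedy constraint propagation: the
#' \code{assigned} matrix marks IDs proven present in a tracklet, the
#' \code{possible} matrix marks IDs not yet excluded. Invariant:
#' assigned implies possible; single-animal tracklets hold at most one
#' assigned ID.
#'
#' @slot ids character vector of ID labels (columns of the matrices).
#' @slot assigned logical matrix, tracklets x IDs.
#' @slot possible logical matrix, tracklets x IDs.
#' @slot provenance character matrix, tracklets x IDs: "classifier",
#'   "propagated" or NA for unassigned pairs.
#' @slot contradicted data.frame of rejected seeds: \code{tracklet},
#'   \code{id}, \code{confidence}.
#' @slot nMutations integer count of state changes (monotonicity audit).
#'
#' @seealso [initStates()], [propagateSeed()], [solveGraph()]
#' @export
setClass("IDSolution",
  representation(ids = "character", assigned = "matrix", possible = "matrix",
                 provenance = "matrix", contradicted = "data.frame",
                 nMutations = "integer"))

setValidity("IDSolution", function(object) {
  msg <- character()
  if (ncol(object@assigned) != length(object@ids) ||
      !identical(dim(object@assigned), dim(object@possible)))
    msg <- c(msg, "assigned/possible must be tracklets x IDs matrices")
  if (any(object@assigned & !object@possible))
    msg <- c(msg, "assigned IDs must be possible")
  if (length(msg)) msg else TRUE
})
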