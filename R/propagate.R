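# Greedy iterative ID propagation on the tracklet graph.
#
# Every node carries a dynamic set of assigned IDs (proven present) and
# possible IDs (not yet excluded). Classifier-labeled tracklets are seeds,
# applied in descending confidence order; after each seed the rule set
# below is run to a fixpoint. Only non-ambiguous propagation is performed;
# whenever a contradiction arises the offending (lower-confidence) seed
# and everything derived in its round are rolled back.
#
# Rules:
#  R1 positive-vertical: an assigned ID must continue into exactly one
#     successor (and come from exactly one predecessor); when only one
#     candidate remains, assign it; with several, do nothing (ambiguous);
#     with none, contradiction (unless the node ends/starts exempt).
#  R2 negative-vertical: an ID with no possible predecessor (successor)
#     cannot be possible in a non-exempt node.
#  R3 horizontal: an assigned ID is impossible in every time-overlapping
#     node (a tracklet's composition is constant over its whole span).
#  R4 capacity/counting: a single-animal node holds exactly one ID; under
#     full coverage (closed ROI, every animal detected every frame), an ID
#     possible in only one node covering some frame must be there.
#  R5 boundary: nodes starting at frame 1, ending at the last frame,
#     flagged at an open ROI boundary, or with no incident edge on that
#     side, are exempt from the vertical rules on that side.

.propCtx <- function(graph, ids, fullCoverage = NA) {
  nd <- trackletNodes(graph); ed <- trackletEdges(graph)
  V <- nrow(nd); Tn <- nFrames(graph)
  succ <- rep(list(integer(0)), V); pred <- rep(list(integer(0)), V)
  if (nrow(ed)) {
    succ[] <- split(ed$to, factor(ed$from, levels = seq_len(V)))
    pred[] <- split(ed$from, factor(ed$to, levels = seq_len(V)))
  }
  indeg <- lengths(pred); outdeg <- lengths(succ)
  openArena <- any(nd$startsOpen) || any(nd$endsOpen)
  if (is.na(fullCoverage)) fullCoverage <- !openArena
  ir <- IRanges::IRanges(start = nd$start, end = nd$end)
  hits <- IRanges::findOverlaps(ir, ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh != sh
  over <- rep(list(integer(0)), V)
  if (any(keep))
    over[] <- split(sh[keep], factor(qh[keep], levels = seq_len(V)))
  list(V = V, K = length(ids), ids = ids, Tn = Tn,
       succ = succ, pred = pred, over = over,
       start = nd$start, end = nd$end,
       isSingle = nd$kind == "single",
       startEx = nd$start == 1L | nd$startsOpen | indeg == 0L,
       endEx = nd$end == Tn | nd$endsOpen | outdeg == 0L,
       fullCoverage = fullCoverage)
}

.newPropState <- function(ctx) {
  st <- new.env(parent = emptyenv())
  st$P <- matrix(TRUE, ctx$V, ctx$K, dimnames = list(NULL, ctx$ids))
  st$S <- matrix(FALSE, ctx$V, ctx$K, dimnames = list(NULL, ctx$ids))
  st$prov <- matrix(NA_character_, ctx$V, ctx$K,
                    dimnames = list(NULL, ctx$ids))
  st$Hdone <- matrix(FALSE, ctx$V, ctx$K)   # horizontal rule bookkeeping
  st$mut <- 0L
  st$contra <- NULL
  st
}

.snapshotState <- function(st)
  list(P = st$P, S = st$S, prov = st$prov, Hdone = st$Hdone, mut = st$mut)

.restoreState <- function(st, snap) {
  st$P <- snap$P; st$S <- snap$S; st$prov <- snap$prov
  st$Hdone <- snap$Hdone; st$mut <- snap$mut; st$contra <- NULL
}

.removePossible <- function(ctx, st, v, i) {
  if (!st$P[v, i]) return(invisible())
  if (st$S[v, i]) {
    st$contra <- list(tracklet = v, id = ctx$ids[i],
                      reason = "assigned ID excluded")
    return(invisible())
  }
  st$P[v, i] <- FALSE
  st$mut <- st$mut + 1L
  invisible()
}

.assign <- function(ctx, st, v, i, prov) {
  if (!st$P[v, i]) {
    st$contra <- list(tracklet = v, id = ctx$ids[i],
                      reason = "assignment of an excluded ID")
    return(invisible())
  }
  if (!st$S[v, i]) {
    st$S[v, i] <- TRUE
    st$prov[v, i] <- prov
    st$mut <- st$mut + 1L
  } else if (prov == "classifier") {
    st$prov[v, i] <- prov
  }
  invisible()
}

.ruleCapacitySingle <- function(ctx, st) {
  rows <- which(ctx$isSingle & rowSums(st$S) > 0L)
  for (v in rows) {
    ii <- which(st$S[v, ])
    if (length(ii) > 1L) {
      st$contra <- list(tracklet = v, id = ctx$ids[ii[2L]],
                        reason = "two IDs assigned to a single-animal tracklet")
      return(invisible())
    }
    for (j in which(st$P[v, ])) if (j != ii) .removePossible(ctx, st, v, j)
    if (!is.null(st$contra)) return(invisible())
  }
  invisible()
}

.ruleHorizontal <- function(ctx, st) {
  todo <- which(st$S & !st$Hdone, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    v <- todo[r, 1L]; i <- todo[r, 2L]
    for (u in ctx$over[[v]]) {
      .removePossible(ctx, st, u, i)
      if (!is.null(st$contra)) return(invisible())
    }
    st$Hdone[v, i] <- TRUE
  }
  invisible()
}

.ruleNegativeVertical <- function(ctx, st) {
  for (v in seq_len(ctx$V)) {
    if (!ctx$startEx[v]) {
      pp <- ctx$pred[[v]]
      av <- if (length(pp) == 1L) st$P[pp, ]
            else colSums(st$P[pp, , drop = FALSE]) > 0L
      for (i in which(st$P[v, ] & !av)) {
        .removePossible(ctx, st, v, i)
        if (!is.null(st$contra)) return(invisible())
      }
    }
    if (!ctx$endEx[v]) {
      ss <- ctx$succ[[v]]
      av <- if (length(ss) == 1L) st$P[ss, ]
            else colSums(st$P[ss, , drop = FALSE]) > 0L
      for (i in which(st$P[v, ] & !av)) {
        .removePossible(ctx, st, v, i)
        if (!is.null(st$contra)) return(invisible())
      }
    }
  }
  invisible()
}

.rulePositiveVertical <- function(ctx, st) {
  asg <- which(st$S, arr.ind = TRUE)
  asg <- asg[order(asg[, 1L], asg[, 2L]), , drop = FALSE]
  for (r in seq_len(nrow(asg))) {
    v <- asg[r, 1L]; i <- asg[r, 2L]
    if (!ctx$endEx[v]) {
      cand <- ctx$succ[[v]][st$P[ctx$succ[[v]], i]]
      if (length(cand) == 0L) {
        st$contra <- list(tracklet = v, id = ctx$ids[i],
                          reason = "assigned ID has no possible successor")
        return(invisible())
      }
      if (length(cand) == 1L && !st$S[cand, i]) {
        .assign(ctx, st, cand, i, "propagated")
        if (!is.null(st$contra)) return(invisible())
      }
    }
    if (!ctx$startEx[v]) {
      cand <- ctx$pred[[v]][st$P[ctx$pred[[v]], i]]
      if (length(cand) == 0L) {
        st$contra <- list(tracklet = v, id = ctx$ids[i],
                          reason = "assigned ID has no possible predecessor")
        return(invisible())
      }
      if (length(cand) == 1L && !st$S[cand, i]) {
        .assign(ctx, st, cand, i, "propagated")
        if (!is.null(st$contra)) return(invisible())
      }
    }
  }
  invisible()
}

.ruleCounting <- function(ctx, st) {
  if (!ctx$fullCoverage || ctx$V == 0L) return(invisible())
  for (i in seq_len(ctx$K)) {
    poss <- which(st$P[, i])
    d <- integer(ctx$Tn + 1L)
    for (v in poss) {
      d[ctx$start[v]] <- d[ctx$start[v]] + 1L
      if (ctx$end[v] < ctx$Tn) d[ctx$end[v] + 1L] <- d[ctx$end[v] + 1L] - 1L
    }
    cov <- cumsum(d[seq_len(ctx$Tn)])
    if (any(cov == 0L)) {
      st$contra <- list(tracklet = NA_integer_, id = ctx$ids[i],
                        reason = "ID has no possible tracklet at some frame")
      return(invisible())
    }
    ones <- cumsum(c(0L, cov == 1L))   # prefix counts of singleton frames
    for (v in poss) {
      if (st$S[v, i]) next
      if (ones[ctx$end[v] + 1L] - ones[ctx$start[v]] > 0L) {
        .assign(ctx, st, v, i, "propagated")
        if (!is.null(st$contra)) return(invisible())
      }
    }
  }
  invisible()
}

.propagateFixpoint <- function(ctx, st) {
  repeat {
    before <- st$mut
    .ruleCapacitySingle(ctx, st); if (!is.null(st$contra)) return(invisible())
    .ruleHorizontal(ctx, st); if (!is.null(st$contra)) return(invisible())
    .ruleNegativeVertical(ctx, st); if (!is.null(st$contra)) return(invisible())
    .rulePositiveVertical(ctx, st); if (!is.null(st$contra)) return(invisible())
    .ruleCounting(ctx, st); if (!is.null(st$contra)) return(invisible())
    if (st$mut == before) break
  }
  invisible()
}

.stateToSolution <- function(ctx, st, contradicted) {
  methods::new("IDSolution", ids = ctx$ids, assigned = st$S, possible = st$P,
               provenance = st$prov, contradicted = contradicted,
               nMutations = as.integer(st$mut))
}

.stateFromSolution <- function(ctx, sol) {
  st <- .newPropState(ctx)
  st$P <- sol@possible; st$S <- sol@assigned; st$prov <- sol@provenance
  st$mut <- sol@nMutations
  st
}

#' Initialize the propagation state
#'
#' Every node starts with all IDs possible and none assigned.
#'
#' @param graph a \linkS4class{TrackletGraph}.
#' @param ids character vector of ID labels (non-empty).
#' @return an \linkS4class{IDSolution} in its initial state.
#' @export
initStates <- function(graph, ids) {
  if (!length(ids)) stop("'ids' must be non-empty")
  ctx <- .propCtx(graph, ids)
  st <- .newPropState(ctx)
  .stateToSolution(ctx, st,
                   data.frame(tracklet = integer(0), id = character(0),
                              confidence = numeric(0)))
}

#' Rank classifier seeds by confidence
#'
#' Orders labeled tracklets by descending classification confidence; ties
#' break by earlier start frame, then lower tracklet id (deterministic).
#'
#' @param graph a classified \linkS4class{TrackletGraph} (or its node
#'   table).
#' @return data.frame `tracklet`, `id`, `confidence` in application order.
#' @export
rankSeeds <- function(graph) {
  nd <- if (methods::is(graph, "TrackletGraph")) trackletNodes(graph)
        else graph
  lab <- nd[!is.na(nd$label), , drop = FALSE]
  lab <- lab[order(-lab$confidence, lab$start, lab$tracklet), , drop = FALSE]
  data.frame(tracklet = lab$tracklet, id = lab$label,
             confidence = lab$confidence, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Propagate a single seed assignment
#'
#' Assigns `id` to `tracklet` and runs the rule set to a fixpoint. On
#' contradiction the seed's whole round is rolled back and the pair is
#' recorded in the solution's `contradicted` table.
#'
#' @param graph a \linkS4class{TrackletGraph}.
#' @param state an \linkS4class{IDSolution}.
#' @param tracklet node id to seed.
#' @param id ID label to assign.
#' @param confidence seed confidence (bookkeeping only).
#' @param fullCoverage enable the per-frame counting rule; defaults to
#'   TRUE for closed-boundary graphs.
#' @return the updated \linkS4class{IDSolution}.
#' @export
propagateSeed <- function(graph, state, tracklet, id, confidence = NA_real_,
                          fullCoverage = NA) {
  ctx <- .propCtx(graph, idLabels(state), fullCoverage)
  if (length(tracklet) != 1L || tracklet < 1L || tracklet > ctx$V)
    stop("seed references an unknown tracklet")
  i <- match(id, ctx$ids)
  if (is.na(i)) stop("seed references an unknown ID")
  st <- .stateFromSolution(ctx, state)
  contradicted <- state@contradicted
  snap <- .snapshotState(st)
  .assign(ctx, st, tracklet, i, "classifier")
  if (is.null(st$contra)) .propagateFixpoint(ctx, st)
  if (!is.null(st$contra)) {
    .restoreState(st, snap)
    contradicted <- rbind(contradicted,
                          data.frame(tracklet = tracklet, id = id,
                                     confidence = confidence))
  }
  .stateToSolution(ctx, st, contradicted)
}

#' Solve the tracklet graph by greedy iterative propagation
#'
#' Applies classifier seeds in rank order, each followed by a propagation
#' fixpoint; the outer loop repeats until a full pass changes nothing.
#' Contradicted seeds are rolled back and recorded; all other assignments
#' are sound with respect to the rule set (see [oracleSolve()] for the
#' exhaustive check used in testing).
#'
#' @param graph a classified \linkS4class{TrackletGraph}.
#' @param ids character vector of all ID labels; defaults to the labels
#'   seen among the graph's classifications.
#' @param seeds optional seed table (as from [rankSeeds()]); defaults to
#'   the graph's own classifications.
#' @param fullCoverage enable the per-frame counting rule; defaults to
#'   TRUE when no tracklet touches an open boundary.
#' @param propagate with FALSE, only the classifier seeds are applied and
#'   no inference is performed (the "without graph propagation" baseline
#'   used to quantify what the graph contributes).
#' @param maxPasses safety cap on outer passes.
#' @return an \linkS4class{IDSolution}.
#' @export
solveGraph <- function(graph, ids = NULL, seeds = NULL, fullCoverage = NA,
                       propagate = TRUE, maxPasses = 100L) {
  if (is.null(seeds)) seeds <- rankSeeds(graph)
  if (is.null(ids)) ids <- sort(unique(seeds$id))
  if (!length(ids)) {
    if (nTracklets(graph) == 0L) return(initStates0(graph))
    stop("no IDs to propagate: supply 'ids' or classify the graph first")
  }
  ctx <- .propCtx(graph, ids, fullCoverage)
  st <- .newPropState(ctx)
  contradicted <- data.frame(tracklet = integer(0), id = character(0),
                             confidence = numeric(0))
  blocked <- character(0)
  if (!propagate) {
    for (r in seq_len(nrow(seeds))) {
      i <- match(seeds$id[r], ids)
      if (!is.na(i)) .assign(ctx, st, seeds$tracklet[r], i, "classifier")
    }
    return(.stateToSolution(ctx, st, contradicted))
  }
  .propagateFixpoint(ctx, st)
  if (!is.null(st$contra))
    stop("inconsistent tracklet graph: ", st$contra$reason)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    before <- st$mut
    for (r in seq_len(nrow(seeds))) {
      v <- seeds$tracklet[r]; i <- match(seeds$id[r], ids)
      if (is.na(i)) stop("seed references an unknown ID: ", seeds$id[r])
      key <- paste(v, i)
      if (key %in% blocked) next
      if (st$S[v, i]) { st$prov[v, i] <- "classifier"; next }
      snap <- .snapshotState(st)
      .assign(ctx, st, v, i, "classifier")
      if (is.null(st$contra)) .propagateFixpoint(ctx, st)
      if (!is.null(st$contra)) {
        .restoreState(st, snap)
        blocked <- c(blocked, key)
        contradicted <- rbind(contradicted,
                              data.frame(tracklet = v, id = seeds$id[r],
                                         confidence = seeds$confidence[r]))
      }
    }
    if (st$mut == before || pass >= maxPasses) break
  }
  .stateToSolution(ctx, st, contradicted)
}

# empty-graph solution (no tracklets, no ids known)
initStates0 <- function(graph) {
  methods::new("IDSolution", ids = character(0),
               assigned = matrix(FALSE, 0, 0), possible = matrix(TRUE, 0, 0),
               provenance = matrix(NA_character_, 0, 0),
               contradicted = data.frame(tracklet = integer(0),
                                         id = character(0),
                                         confidence = numeric(0)),
               nMutations = 0L)
}

#' Serialize a solution as CSV tables
#'
#' Writes `assignments.csv` (tracklet, id, provenance) and
#' `contradictions.csv`.
#'
#' @param solution an \linkS4class{IDSolution}.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSolution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- which(solution@assigned, arr.ind = TRUE)
  asg <- data.frame(tracklet = idx[, 1L],
                    id = solution@ids[idx[, 2L]],
                    provenance = solution@provenance[idx])
  asg <- asg[order(asg$tracklet, asg$id), , drop = FALSE]
  write.csv(asg, file.path(dir, "assignments.csv"), row.names = FALSE)
  write.csv(solution@contradicted, file.path(dir, "contradictions.csv"),
            row.names = FALSE)
  invisible(dir)
}
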