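# Exhaustive enumeration oracle for the propagation solver, plus
# generators for abstract tracklet-graph fixtures. The oracle enumerates
# every complete, consistent identity composition of a small graph and
# returns the assignments common to all of them (the "forced set"): a
# sound propagation algorithm may only ever make assignments inside it.

#' Construct a tracklet graph from bare node and edge tables
#'
#' For fixtures and for users bringing their own tracker output: builds a
#' \linkS4class{TrackletGraph} with stub blob tables (no masks or crops).
#'
#' @param nodes data.frame with at least `start` and `end`; optional
#'   `kind`, `label`, `confidence`, `startsOpen`, `endsOpen`.
#' @param edges data.frame `from`, `to` (may be empty).
#' @param nFrames total frame count (default max end).
#' @param frameDim c(height, width) bookkeeping value.
#' @return a \linkS4class{TrackletGraph}.
#' @export
makeTrackletGraph <- function(nodes, edges = NULL, nFrames = NULL,
                              frameDim = c(1L, 1L)) {
  V <- nrow(nodes)
  if (is.null(edges)) edges <- data.frame(from = integer(0), to = integer(0))
  if (is.null(nFrames)) nFrames <- if (V) max(nodes$end) else 0L
  nd <- data.frame(tracklet = seq_len(V),
                   start = as.integer(nodes$start),
                   end = as.integer(nodes$end),
                   nBlobs = as.integer(nodes$end - nodes$start + 1L),
                   kind = if (!is.null(nodes$kind)) nodes$kind
                          else rep("unknown", V),
                   label = if (!is.null(nodes$label)) nodes$label
                           else rep(NA_character_, V),
                   confidence = if (!is.null(nodes$confidence))
                     nodes$confidence else rep(NA_real_, V),
                   startsOpen = if (!is.null(nodes$startsOpen))
                     nodes$startsOpen else rep(FALSE, V),
                   endsOpen = if (!is.null(nodes$endsOpen))
                     nodes$endsOpen else rep(FALSE, V),
                   stringsAsFactors = FALSE)
  blobs <- lapply(seq_len(V), function(i) {
    fr <- seq.int(nd$start[i], nd$end[i])
    b <- data.frame(frame = fr, x = NA_real_, y = NA_real_,
                    area = NA_integer_, orient = NA_real_)
    b$mask <- rep(list(integer(0)), length(fr))
    b$crop <- rep(list(NULL), length(fr))
    b
  })
  methods::new("TrackletGraph", nodes = nd,
               edges = data.frame(from = as.integer(edges$from),
                                  to = as.integer(edges$to)),
               blobs = blobs, nFrames = as.integer(nFrames),
               frameDim = as.integer(frameDim))
}

# enumerate all frame-complete chains (paths start-of-video to
# end-of-video, or boundary-exempt endpoints) through the graph
.enumChains <- function(ctx) {
  chains <- list()
  walk <- function(path, v) {
    if (ctx$endEx[v]) chains[[length(chains) + 1L]] <<- c(path, v)
    for (u in ctx$succ[[v]]) walk(c(path, v), u)
  }
  for (v in which(ctx$startEx)) walk(integer(0), v)
  chains
}

#' Exhaustively enumerate consistent compositions (test oracle)
#'
#' Enumerates every complete assignment in which each ID traces a chain of
#' tracklets through the graph (respecting edges, time exclusivity and
#' boundary exemptions), every tracklet contains at least one ID,
#' single-animal tracklets exactly one, and multi-animal tracklets at
#' least two, subject to the given seed assignments. Returns the forced
#' set: pairs assigned in every consistent completion. Intended for small
#' graphs (roughly <= 15 nodes, <= 5 IDs).
#'
#' @param graph a \linkS4class{TrackletGraph}.
#' @param seeds data.frame `tracklet`, `id` of fixed assignments (may be
#'   empty).
#' @param ids character vector of all ID labels.
#' @return list: `forced` (logical tracklets x IDs matrix),
#'   `nCompletions` (count of consistent completions).
#' @export
oracleSolve <- function(graph, seeds, ids) {
  ctx <- .propCtx(graph, ids)
  V <- ctx$V; K <- ctx$K
  if (V == 0L)
    return(list(forced = matrix(FALSE, 0L, 0L), nCompletions = 1L))
  chains <- .enumChains(ctx)
  if (!length(chains)) stop("no chains through the graph: inconsistent fixture")
  # membership matrix: chain x node
  mem <- matrix(FALSE, length(chains), V)
  for (c in seq_along(chains)) mem[c, chains[[c]]] <- TRUE
  # chains admissible per ID given the seeds
  chainSets <- lapply(seq_len(K), function(i) {
    need <- seeds$tracklet[seeds$id == ids[i]]
    ok <- seq_along(chains)
    for (v in need) ok <- ok[mem[ok, v]]
    ok
  })
  if (any(lengths(chainSets) == 0L))
    stop("no consistent completion: a seeded ID has no admissible chain")
  kindSingle <- ctx$isSingle
  kindMulti <- trackletNodes(graph)$kind == "multi"
  forced <- matrix(TRUE, V, K, dimnames = list(NULL, ids))
  nComp <- 0L
  counts <- integer(V)
  recurse <- function(i, membership) {
    if (i > K) {
      cnt <- colSums(membership)
      if (any(cnt == 0L)) return(invisible())
      if (any(kindSingle & cnt != 1L)) return(invisible())
      if (any(kindMulti & cnt < 2L)) return(invisible())
      nComp <<- nComp + 1L
      forced <<- forced & t(membership)
      return(invisible())
    }
    for (c in chainSets[[i]]) {
      membership[i, ] <- mem[c, ]
      recurse(i + 1L, membership)
    }
  }
  recurse(1L, matrix(FALSE, K, V))
  if (nComp == 0L)
    stop("no consistent completion: inconsistent fixture or seed set")
  list(forced = forced, nCompletions = nComp)
}

#' Simulate a random abstract tracklet graph with known compositions
#'
#' Evolves a partition of `nIds` animals over `nFrames` frames: at each
#' frame, with the given probabilities, two groups merge or one group
#' splits, closing and opening tracklets exactly as the tracker's update
#' rules would. Returns the graph together with the true composition of
#' every tracklet -- the substrate for randomized soundness testing of the
#' propagation solver against [oracleSolve()].
#'
#' @param nIds number of animals.
#' @param nFrames number of frames.
#' @param pMerge,pSplit per-frame event probabilities.
#' @param seed RNG seed.
#' @return list: `graph` (a \linkS4class{TrackletGraph} with `kind` set
#'   from the true compositions), `comps` (list of ID index vectors per
#'   tracklet), `ids` (labels "id1"..).
#' @export
simulateTrackletGraph <- function(nIds, nFrames, pMerge = 0.35,
                                  pSplit = 0.3, seed = 1) {
  stopifnot(nIds >= 1L, nFrames >= 1L)
  ids <- paste0("id", seq_len(nIds))
  .withSeed(seed, {
    groups <- as.list(seq_len(nIds))          # partition: list of ID vectors
    trkOf <- integer(length(groups))          # open tracklet per group
    start <- integer(0); end <- integer(0); comps <- list()
    edges <- data.frame(from = integer(0), to = integer(0))
    openT <- integer(0)
    for (g in seq_along(groups)) {
      comps[[g]] <- groups[[g]]; start[g] <- 1L; end[g] <- NA_integer_
      trkOf[g] <- g
    }
    nextId <- length(groups) + 1L
    for (t in 2:max(nFrames, 2L)) {
      if (t > nFrames) break
      changedOld <- integer(0)   # group indices that close
      newGroups <- NULL
      u <- runif(1)
      if (u < pMerge && length(groups) >= 2L) {
        pick <- sample.int(length(groups), 2L)
        merged <- sort(c(groups[[pick[1L]]], groups[[pick[2L]]]))
        changedOld <- pick
        newGroups <- list(merged)
      } else if (u < pMerge + pSplit) {
        big <- which(lengths(groups) >= 2L)
        if (length(big)) {
          g <- big[sample.int(length(big), 1L)]
          members <- groups[[g]]
          k <- sample.int(length(members) - 1L, 1L)
          side <- sample(members, k)
          changedOld <- g
          newGroups <- list(sort(side), sort(setdiff(members, side)))
        }
      }
      if (length(changedOld)) {
        for (g in changedOld) end[trkOf[g]] <- t - 1L
        newIds <- integer(length(newGroups))
        for (n in seq_along(newGroups)) {
          newIds[n] <- nextId
          start[nextId] <- t; end[nextId] <- NA_integer_
          comps[[nextId]] <- newGroups[[n]]
          nextId <- nextId + 1L
        }
        for (g in changedOld) for (n in seq_along(newGroups)) {
          if (length(intersect(groups[[g]], newGroups[[n]])))
            edges <- rbind(edges, data.frame(from = trkOf[g], to = newIds[n]))
        }
        groups <- c(groups[-changedOld], newGroups)
        trkOf <- c(trkOf[-changedOld], newIds)
      }
    }
    end[is.na(end)] <- nFrames
    end[trkOf] <- nFrames
    V <- nextId - 1L
    nodes <- data.frame(start = start[seq_len(V)], end = end[seq_len(V)],
                        kind = ifelse(lengths(comps) == 1L, "single", "multi"))
    g <- makeTrackletGraph(nodes, edges, nFrames = nFrames)
    list(graph = g, comps = comps[seq_len(V)], ids = ids)
  })
}
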