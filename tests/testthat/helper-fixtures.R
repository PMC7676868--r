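# Shared fixtures, built once per test session and cached.

.cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# two agents approaching head-on, dwelling in contact, then separating:
# the canonical merge/split motif (5 tracklets, 4 edges)
motifSim <- function() .cached("motifSim", {
  ag <- colonyAgents(2, colors = c("B", "G", "O", "P"), nTags = 2)
  arena <- arenaSpec(120, 80)
  d <- c(seq(37, 13, by = -4), rep(13, 5), seq(17, 37, by = 4))
  tr <- do.call(rbind, lapply(seq_along(d), function(t) rbind(
    data.frame(frame = t, id = ag$id[1], x = 60 - d[t] / 2, y = 40,
               heading = 0),
    data.frame(frame = t, id = ag$id[2], x = 60 + d[t] / 2, y = 40,
               heading = pi))))
  scriptedColony(ag, arena, tr)
})

motifGraph <- function() .cached("motifGraph", {
  sim <- motifSim()
  buildTrackletGraph(frameSource(sim, noiseSd = 0.01),
                     bg = list(image = arenaBackground(sim@arena)))
})

# abstract version of the same motif for solver-level tests
motifAbstractGraph <- function() {
  makeTrackletGraph(
    data.frame(start = c(1, 1, 6, 11, 11), end = c(5, 5, 10, 15, 15),
               kind = c("single", "single", "multi", "single", "single")),
    data.frame(from = c(1, 2, 3, 3), to = c(3, 3, 4, 5)), nFrames = 15)
}

# small aggregating colony, tracked end to end with the oracle classifier
colonyCase <- function() .cached("colonyCase", {
  sim <- simulateColony(colonyAgents(4), arenaSpec(160, 160), nFrames = 150,
                        motion = list(attraction = 0.6), seed = 21)
  graph <- buildTrackletGraph(frameSource(sim),
                              bg = list(image = arenaBackground(sim@arena)),
                              searchPx = 6,
                              classifier = oracleClassifier(sim))
  graph <- classifyTracklets(graph)
  sol <- solveGraph(graph, ids = agentTable(sim)$id)
  list(sim = sim, graph = graph, sol = sol,
       traj = exportTrajectories(sol, graph))
})

# random abstract tracklet graph plus true-composition seeds
randomGraphCase <- function(seed, maxNodes = 12) {
  nIds <- 2 + seed %% 3
  fx <- simulateTrackletGraph(nIds, nFrames = 10 + seed %% 6, seed = seed)
  if (nTracklets(fx$graph) > maxNodes) return(NULL)
  singles <- which(trackletNodes(fx$graph)$kind == "single")
  if (!length(singles)) return(NULL)
  ns <- max(1L, length(singles) %/% 2L)
  pick <- withr::with_seed(seed, sample(singles, ns))
  conf <- withr::with_seed(seed + 1L, runif(ns))
  fx$seeds <- data.frame(
    tracklet = pick,
    id = fx$ids[vapply(fx$comps[pick], `[`, integer(1), 1L)],
    confidence = conf)
  fx
}

# blob membership of every true agent at one frame of a graph
gtMembers <- function(graph, gt, v, j) {
  b <- trackletBlobs(graph)[[v]]
  g <- gt[gt$frame == b$frame[j] & gt$present, , drop = FALSE]
  h <- graph@frameDim[1]; w <- graph@frameDim[2]
  lab <- integer(h * w); lab[b$mask[[j]]] <- 1L
  g$id[tracktags:::.labelAt(lab, as.integer(round(g$x)),
                            as.integer(round(g$y)), h, w) == 1L]
}

# the benchmark colony condition: 16 double-tagged agents, 2000 frames,
# closed 256x256 arena, aggregation on; tracked end to end with the
# zero-corruption oracle classifier
small16Case <- function() .cached("small16", {
  sim <- smallColonySim(nFrames = 2000)
  graph <- buildTrackletGraph(frameSource(sim), searchPx = 6,
                              bgSamples = 25,
                              classifier = oracleClassifier(sim))
  graph <- classifyTracklets(graph)
  ids <- agentTable(sim)$id
  sol <- solveGraph(graph, ids = ids)
  solNoProp <- solveGraph(graph, ids = ids, propagate = FALSE)
  list(sim = sim, graph = graph, sol = sol,
       traj = exportTrajectories(sol, graph),
       trajNoProp = exportTrajectories(solNoProp, graph))
})
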