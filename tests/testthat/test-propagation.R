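test_that("initial state marks every ID possible and none assigned", {
  g <- motifAbstractGraph()
  st <- initStates(g, c("red", "blue", "green"))
  expect_true(all(possibleIDs(st)))
  expect_false(any(assignedIDs(st)))
  expect_equal(dim(assignedIDs(st)), c(5, 3))
  expect_error(initStates(g, character(0)), "non-empty")
})

test_that("seeds rank by confidence with deterministic tie-breaks", {
  nd <- data.frame(tracklet = 1:4, start = c(5, 1, 9, 2), end = c(6, 2, 10, 3),
                   label = c("a", "b", "c", "d"),
                   confidence = c(0.9, 0.5, 0.99, 0.5))
  rk <- rankSeeds(nd)
  expect_equal(rk$id, c("c", "a", "b", "d"))  # 0.5 tie: earlier start first
  expect_equal(nrow(rankSeeds(nd[0, ])), 0)
})

test_that("a forced chain of single-animal tracklets propagates its seed", {
  g <- makeTrackletGraph(
    data.frame(start = c(1, 4, 8), end = c(3, 7, 10),
               kind = "single"),
    data.frame(from = c(1, 2), to = c(2, 3)), nFrames = 10)
  # abstract chain fixture: coverage is incomplete by construction, so
  # the per-frame counting rule is switched off
  sol <- solveGraph(g, ids = c("red", "blue"), fullCoverage = FALSE,
                    seeds = data.frame(tracklet = 1, id = "red",
                                       confidence = 1))
  expect_true(all(assignedIDs(sol)[, "red"]))
  expect_equal(unname(sol@provenance[, "red"]),
               c("classifier", "propagated", "propagated"))
})

test_that("the merge/split motif resolves exactly as the exhaustive oracle forces", {
  g <- motifAbstractGraph()
  ids <- c("red", "blue")
  seeds <- data.frame(tracklet = c(1, 4), id = c("red", "red"),
                      confidence = c(0.9, 0.8))
  sol <- solveGraph(g, ids = ids, seeds = seeds)
  orc <- oracleSolve(g, seeds, ids)
  expect_equal(orc$nCompletions, 1)
  expect_identical(unname(assignedIDs(sol)), unname(orc$forced))
  # tau3 holds both IDs; tau2 and tau5 are forced to blue
  expect_true(all(assignedIDs(sol)[3, ]))
  expect_true(assignedIDs(sol)[2, "blue"])
  expect_true(assignedIDs(sol)[5, "blue"])
})

test_that("an inconsistent lowest-confidence seed is contradicted and rolled back", {
  g <- motifAbstractGraph()
  seeds <- data.frame(tracklet = c(1, 5, 4), id = "red",
                      confidence = c(0.9, 0.8, 0.4))
  sol <- solveGraph(g, ids = c("red", "blue"), seeds = seeds)
  expect_equal(sol@contradicted$tracklet, 4)
  expect_equal(sol@contradicted$id, "red")
  expect_true(assignedIDs(sol)[5, "red"])
  expect_true(assignedIDs(sol)[4, "blue"])   # resolved despite the bad seed
})

test_that("propagateSeed applies one seed at a time and states stay monotone", {
  g <- motifAbstractGraph()
  ids <- c("red", "blue")
  st <- initStates(g, ids)
  st1 <- propagateSeed(g, st, 1, "red", confidence = 0.9)
  expect_true(all(possibleIDs(st1) <= possibleIDs(st)))
  expect_true(all(assignedIDs(st1) >= assignedIDs(st)))
  st2 <- propagateSeed(g, st1, 4, "red", confidence = 0.8)
  expect_true(all(possibleIDs(st2) <= possibleIDs(st1)))
  expect_true(all(assignedIDs(st2) >= assignedIDs(st1)))
  expect_error(propagateSeed(g, st, 99, "red"), "unknown tracklet")
  expect_error(propagateSeed(g, st, 1, "mauve"), "unknown ID")
})

test_that("with no classifications nothing is assigned", {
  # every frame is covered by two nodes here, so not even the counting
  # rule can act without a seed
  g <- makeTrackletGraph(
    data.frame(start = c(1, 1, 5, 5), end = c(4, 4, 9, 9), kind = "single"),
    data.frame(from = c(1, 1, 2, 2), to = c(3, 4, 3, 4)), nFrames = 9)
  sol <- solveGraph(g, ids = c("red", "blue"),
                    seeds = data.frame(tracklet = integer(0),
                                       id = character(0),
                                       confidence = numeric(0)))
  expect_false(any(assignedIDs(sol)))
  expect_true(all(possibleIDs(sol)))
})

test_that("a genuinely ambiguous split stays unassigned in solver and oracle", {
  # one single splits into two identical single continuations
  g <- makeTrackletGraph(
    data.frame(start = c(1, 1, 5, 5), end = c(4, 4, 9, 9), kind = "single"),
    data.frame(from = c(1, 1, 2, 2), to = c(3, 4, 3, 4)), nFrames = 9)
  seeds <- data.frame(tracklet = 1, id = "red", confidence = 1)
  ids <- c("red", "blue")
  sol <- solveGraph(g, ids = ids, seeds = seeds)
  orc <- oracleSolve(g, seeds, ids)
  expect_false(any(assignedIDs(sol)[3:4, ]))
  expect_false(any(orc$forced[3:4, ]))
  expect_gt(orc$nCompletions, 1)
})

test_that("oracleSolve reports impossible seed sets and handles single nodes", {
  g1 <- makeTrackletGraph(data.frame(start = 1, end = 5, kind = "single"))
  orc <- oracleSolve(g1, data.frame(tracklet = 1, id = "red"), "red")
  expect_true(orc$forced[1, "red"])
  expect_equal(orc$nCompletions, 1)
  g2 <- motifAbstractGraph()
  expect_error(
    oracleSolve(g2, data.frame(tracklet = c(1, 2), id = c("red", "red")),
                c("red", "blue")),
    "no consistent completion")
})

test_that("solver assignments are always inside the oracle's forced set", {
  nGraphs <- 0; violations <- 0
  for (s in 1:150) {
    fx <- randomGraphCase(s)
    if (is.null(fx)) next
    nGraphs <- nGraphs + 1
    sol <- solveGraph(fx$graph, ids = fx$ids, seeds = fx$seeds)
    orc <- oracleSolve(fx$graph, fx$seeds, fx$ids)
    violations <- violations + sum(assignedIDs(sol) & !orc$forced)
  }
  expect_gt(nGraphs, 60)
  expect_equal(violations, 0)
})

test_that("state mutations stay within the termination bound", {
  done <- 0
  for (s in 1:40) {
    if (done >= 3) break
    fx <- randomGraphCase(s)
    if (is.null(fx)) next
    done <- done + 1
    sol <- solveGraph(fx$graph, ids = fx$ids, seeds = fx$seeds)
    bound <- 2 * nTracklets(fx$graph) * length(fx$ids)
    expect_lte(sol@nMutations, bound)
    expect_lte(sum(assignedIDs(sol)) + sum(!possibleIDs(sol)), bound)
  }
})

test_that("open-boundary tracklets are exempt from vertical rules on that side", {
  # chain whose tail ends at the open boundary: no contradiction when the
  # animal leaves, and the ID is not forced anywhere after the exit
  g <- makeTrackletGraph(
    data.frame(start = c(1, 4), end = c(3, 6), kind = "single",
               startsOpen = c(FALSE, FALSE), endsOpen = c(FALSE, TRUE)),
    data.frame(from = 1, to = 2), nFrames = 10)
  sol <- solveGraph(g, ids = c("red"), fullCoverage = FALSE,
                    seeds = data.frame(tracklet = 1, id = "red",
                                       confidence = 1))
  expect_true(assignedIDs(sol)[2, "red"])
  expect_equal(nrow(sol@contradicted), 0)
})
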