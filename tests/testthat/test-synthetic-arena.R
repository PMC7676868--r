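test_that("a lone resting agent stays put and a closed ROI keeps everyone present", {
  sim <- simulateColony(colonyAgents(1), arenaSpec(64, 64), nFrames = 10,
                        motion = list(attraction = 0, restProb = 1,
                                      wakeProb = 0), seed = 2)
  gt <- groundTruth(sim)
  expect_equal(sd(gt$x), 0)
  expect_equal(sd(gt$y), 0)
  expect_true(all(gt$present))

  sim2 <- simulateColony(colonyAgents(3), arenaSpec(128, 128), nFrames = 50,
                         seed = 9)
  expect_true(all(groundTruth(sim2)$present))
})

test_that("simulation is deterministic given the seed", {
  a <- simulateColony(colonyAgents(3), arenaSpec(96, 96), nFrames = 40,
                      seed = 5)
  b <- simulateColony(colonyAgents(3), arenaSpec(96, 96), nFrames = 40,
                      seed = 5)
  c <- simulateColony(colonyAgents(3), arenaSpec(96, 96), nFrames = 40,
                      seed = 6)
  expect_identical(groundTruth(a), groundTruth(b))
  expect_false(identical(groundTruth(a), groundTruth(c)))
  expect_identical(renderFrame(a, 7), renderFrame(b, 7))
})

test_that("attraction produces shared aggregates within a few hundred frames", {
  sim <- simulateColony(colonyAgents(2), arenaSpec(128, 128), nFrames = 500,
                        motion = list(attraction = 0.9), seed = 7)
  gt <- groundTruth(sim)
  together <- tapply(gt$aggregate, gt$frame, function(a) a[1] == a[2])
  expect_true(any(together))
  # pairwise-distance oracle: whenever labeled together, bodies are close
  byf <- split(gt, gt$frame)
  for (g in byf[unlist(together)]) {
    d <- sqrt(diff(g$x)^2 + diff(g$y)^2)
    expect_lt(d, max(agentTable(sim)$bodyLength) + 2)
  }
})

test_that("per-frame displacement respects the speed bound", {
  sim <- simulateColony(colonyAgents(5), arenaSpec(160, 160), nFrames = 120,
                        seed = 13)
  gt <- groundTruth(sim)
  spd <- agentTable(sim)$speed[match(gt$id[gt$frame == 1], agentTable(sim)$id)]
  for (id in unique(gt$id)) {
    g <- gt[gt$id == id, ]
    disp <- sqrt(diff(g$x)^2 + diff(g$y)^2)
    # soft-core repulsion may add up to ~1 px on top of the step
    expect_true(all(disp <= agentTable(sim)$speed[1] + 1.5))
  }
})

test_that("aggregate labels equal connected components of the touch graph", {
  sim <- simulateColony(colonyAgents(6), arenaSpec(160, 160), nFrames = 60,
                        motion = list(attraction = 0.8), seed = 3)
  gt <- groundTruth(sim)
  ag <- agentTable(sim)
  # independent oracle: brute-force pairwise capsule distances + BFS
  for (t in c(10, 30, 60)) {
    g <- gt[gt$frame == t, ]
    n <- nrow(g)
    seg <- tracktags:::.bodySegments(g$x, g$y, g$heading, ag$bodyLength,
                                     ag$bodyWidth)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- tracktags:::.segDist(seg[i, 1:2], seg[i, 3:4],
                                seg[j, 1:2], seg[j, 3:4])
      adj[i, j] <- adj[j, i] <- d <= (ag$bodyWidth[i] + ag$bodyWidth[j]) / 2 + 1.5
    }
    comp <- integer(n)
    k <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      k <- k + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] > 0L) next
        comp[v] <- k
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    expect_identical(outer(comp, comp, "=="),
                     outer(g$aggregate, g$aggregate, "=="))
  }
})

test_that("rendering draws agents on the background and empty frames are background plus noise", {
  arena <- arenaSpec(64, 64)
  ag <- colonyAgents(1)
  tr <- data.frame(frame = 1, id = ag$id, x = 32, y = 32, heading = 0)
  sim <- scriptedColony(ag, arena, tr)
  fr <- renderFrame(sim, 1, noiseSd = 0)
  bg <- arenaBackground(arena)
  expect_gt(sum(abs(fr - bg) > 0.2), 30)   # a body got painted
  # an absent-agent frame differs from background only by the stated noise
  sim0 <- scriptedColony(ag, arenaSpec(64, 64, openBoundary = TRUE),
                         data.frame(frame = 1, id = ag$id, x = -50, y = -50,
                                    heading = 0))
  sim0@gt$present <- FALSE
  fr0 <- renderFrame(sim0, 1, noiseSd = 0.02)
  expect_lt(max(abs(fr0 - bg)), 0.02 * 6)
  expect_gt(sd(fr0 - bg), 0.01)
})

test_that("fixtures round-trip through disk and are byte-stable", {
  dir <- withr::local_tempdir()
  sim <- simulateColony(colonyAgents(2), arenaSpec(72, 72), nFrames = 12,
                        seed = 4)
  writeFixture(sim, file.path(dir, "a"))
  writeFixture(sim, file.path(dir, "b"))
  expect_length(list.files(file.path(dir, "a", "frames"), "\\.png$"), 12)
  gt <- readFixtureGT(file.path(dir, "a"))
  expect_equal(gt$x, groundTruth(sim)$x)
  expect_equal(gt$id, groundTruth(sim)$id)
  expect_identical(readBin(file.path(dir, "a", "gt.csv"), "raw", 1e6),
                   readBin(file.path(dir, "b", "gt.csv"), "raw", 1e6))
  src <- frameSourceFromDir(file.path(dir, "a"))
  expect_equal(attr(src, "nFrames"), 12)
  # PNG quantizes to 8 bits; re-read frames agree to that precision
  expect_lt(max(abs(src(3) - renderFrame(sim, 3))), 1 / 255)
})

test_that("invalid simulation inputs are rejected with clear messages", {
  expect_error(simulateColony(colonyAgents(1)[0, ], arenaSpec(64, 64), 10),
               "non-empty")
  expect_error(simulateColony(colonyAgents(1), arenaSpec(64, 64), 0),
               "nFrames")
  expect_error(arenaSpec(-5, 64), "width")
  expect_error(agentSpec("A", list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                   c(1, 1, 0))), "1 to 3")
  expect_error(colonyAgents(20, colors = c("B", "G"), nTags = 1), "distinct")
})
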