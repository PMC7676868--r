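test_that("Clopper-Pearson intervals are exact and well-behaved", {
  expect_equal(clopperPearson(0, 500), c(0, 0.00735), tolerance = 1e-3)
  expect_equal(clopperPearson(6, 500), c(0.0044, 0.026), tolerance = 1e-2)
  expect_equal(clopperPearson(500, 500)[2], 1)
  expect_equal(clopperPearson(0, 10)[1], 0)
  # interval contains the point estimate
  for (k in c(0, 3, 7, 10)) {
    ci <- clopperPearson(k, 10)
    expect_lte(ci[1], k / 10); expect_gte(ci[2], k / 10)
  }
  # width shrinks with n at fixed k/n
  w <- vapply(c(20, 100, 500), function(n) diff(clopperPearson(n / 10, n)),
              numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(clopperPearson(-1, 10), "require")
  expect_error(clopperPearson(11, 10), "require")
  expect_error(clopperPearson(1, 10, alpha = 1.5), "alpha")
})

test_that("assignment rate is assigned rows over IDs x frames", {
  tab <- expand.grid(frame = 1:100, id = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  tab$flag <- "unassigned"
  tab$flag[1:150] <- "single_classified"
  expect_equal(assignmentRate(tab, 3, 100), 0.5)
  tab$flag <- "multi_propagated"
  expect_equal(assignmentRate(tab, 3, 100), 1)
  expect_error(assignmentRate(tab, 0, 100), "positive")
})

test_that("trajectories are gap-free for solitary agents and exclusive across IDs", {
  cs <- colonyCase()
  traj <- cs$traj
  expect_setequal(unique(traj$id), agentTable(cs$sim)$id)
  expect_equal(nrow(traj), 4 * 150)
  # exclusivity: no two IDs share a single_* location at the same frame
  sing <- traj[traj$flag %in% c("single_classified", "single_propagated"), ]
  expect_false(any(duplicated(sing[, c("frame", "tracklet")])))
  # unassigned rows carry no fabricated positions
  un <- traj[traj$flag == "unassigned", ]
  expect_true(all(is.na(un$x)) && all(is.na(un$y)))
  # orientation only on single rows
  expect_true(all(is.na(traj$orientation[traj$flag == "multi_propagated"])))
})

test_that("exported orientations track the true heading when the animal moves", {
  cs <- colonyCase()
  gt <- groundTruth(cs$sim)
  traj <- cs$traj
  gt <- gt[order(gt$id, gt$frame), ]
  gt$spd <- unlist(tapply(seq_len(nrow(gt)), gt$id, function(ix)
    c(0, sqrt(diff(gt$x[ix])^2 + diff(gt$y[ix])^2))))
  key <- paste(gt$frame, gt$id)
  sing <- traj[traj$flag %in% c("single_classified", "single_propagated"), ]
  hit <- match(paste(sing$frame, sing$id), key)
  dmod <- tracktags:::.orientDiff(sing$orientation, gt$heading[hit])
  expect_lt(median(dmod, na.rm = TRUE), 0.1)
  # where the animal clearly moves, head/tail resolves to the true heading
  fast <- which(gt$spd[hit] > 2 & !is.na(sing$orientation))
  expect_gt(length(fast), 30)
  dfull <- abs(tracktags:::.wrapAngle(sing$orientation[fast] -
                                      gt$heading[hit][fast]))
  expect_gte(mean(dfull < pi / 2), 0.95)
})

test_that("census and subsampled error agree with a constructed corruption", {
  cs <- colonyCase()
  traj <- cs$traj
  gt <- groundTruth(cs$sim)
  base <- assignmentError(traj, gt, cs$graph)
  expect_equal(base$assignmentError, 0)
  # swap the locations of two IDs on frames where they are far apart
  ids <- agentTable(cs$sim)$id[1:2]
  sing <- traj$flag %in% c("single_classified", "single_propagated")
  swap <- integer(0)
  for (t in seq_len(nFrames(cs$graph))) {
    r1 <- which(traj$frame == t & traj$id == ids[1] & sing)
    r2 <- which(traj$frame == t & traj$id == ids[2] & sing)
    if (length(r1) && length(r2)) {
      d <- sqrt((traj$x[r1] - traj$x[r2])^2 + (traj$y[r1] - traj$y[r2])^2)
      if (d > 30) swap <- rbind(swap, c(r1, r2))
    }
  }
  expect_gt(nrow(swap), 4)
  nsw <- floor(nrow(swap) * 0.5)
  bad <- traj
  for (k in seq_len(nsw)) {
    r <- swap[k, ]
    bad[r, c("x", "y")] <- bad[rev(r), c("x", "y")]
  }
  err <- assignmentError(bad, gt, cs$graph)
  expect_equal(err$nIncorrect, 2 * nsw)
  # subsample mode judges exactly nPoints, deterministically by seed
  sub1 <- assignmentError(bad, gt, cs$graph, nPoints = 200, seed = 5)
  sub2 <- assignmentError(bad, gt, cs$graph, nPoints = 200, seed = 5)
  expect_equal(sub1$nJudged, 200)
  expect_identical(sub1, sub2)
  expect_lt(abs(sub1$assignmentError - err$assignmentError), 0.1)
  expect_error(assignmentError(traj[traj$flag == "unassigned", ], gt),
               "no assignments")
})
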