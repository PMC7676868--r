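flatBG <- function(h, w, v = 0.9) array(v, c(h, w, 3))

test_that("background is the per-pixel median and tolerates short sequences", {
  bgv <- flatBG(20, 20)
  frames <- rep(list(bgv), 7)
  bg <- estimateBackground(frames, nSamples = 5)
  expect_equal(bg$image, bgv)
  # one agent moving over a static scene occupies each pixel < 50% of samples
  frames2 <- lapply(1:9, function(t) {
    f <- flatBG(20, 20)
    f[5:8, (2 * t):(2 * t + 1), ] <- 0.1
    f
  })
  bg2 <- estimateBackground(frames2, nSamples = 9)
  expect_equal(bg2$image, bgv)
  # more samples requested than frames exist: uses all, no error
  bg3 <- estimateBackground(frames2[1:4], nSamples = 50)
  expect_equal(bg3$nSamples, 4)
  expect_error(estimateBackground(frames2, nSamples = 2), "nSamples")
})

test_that("a frame identical to the background yields no blobs", {
  bg <- estimateBackground(list(flatBG(30, 30)))
  expect_equal(nrow(segmentFrame(flatBG(30, 30), bg, 0.3, 5)), 0)
  expect_error(segmentFrame(flatBG(31, 30), bg, 0.3, 5), "dimensions")
})

test_that("well-separated rendered agents segment into single blobs near truth", {
  ag <- colonyAgents(2)
  arena <- arenaSpec(128, 96)
  tr <- rbind(data.frame(frame = 1, id = ag$id[1], x = 30, y = 30,
                         heading = 0.7),
              data.frame(frame = 1, id = ag$id[2], x = 90, y = 60,
                         heading = 2.2))
  sim <- scriptedColony(ag, arena, tr)
  blobs <- segmentFrame(renderFrame(sim, 1, noiseSd = 0),
                        list(image = arenaBackground(arena)), 0.3, 16)
  expect_equal(nrow(blobs), 2)
  blobs <- blobs[order(blobs$x), ]
  expect_lt(abs(blobs$x[1] - 30) + abs(blobs$y[1] - 30), 2)
  expect_lt(abs(blobs$x[2] - 90) + abs(blobs$y[2] - 60), 2)
  # orientation recovers the heading modulo pi
  expect_lt(tracktags:::.orientDiff(blobs$orient[1], 0.7), 0.1)
  expect_lt(tracktags:::.orientDiff(blobs$orient[2], 2.2), 0.1)
})

test_that("touching agents form one merged blob containing both centroids", {
  ag <- colonyAgents(2)
  arena <- arenaSpec(128, 96)
  tr <- rbind(data.frame(frame = 1, id = ag$id[1], x = 54, y = 40,
                         heading = 0),
              data.frame(frame = 1, id = ag$id[2], x = 66, y = 40,
                         heading = pi))
  sim <- scriptedColony(ag, arena, tr)
  blobs <- segmentFrame(renderFrame(sim, 1, noiseSd = 0),
                        list(image = arenaBackground(arena)), 0.3, 16)
  expect_equal(nrow(blobs), 1)
  h <- 96
  expect_true(all(tracktags:::.xyToPx(c(54, 66), c(40, 40), h) %in%
                    blobs$mask[[1]]))
})

test_that("blob masks are disjoint and foreground shrinks with the threshold", {
  sim <- simulateColony(colonyAgents(5), arenaSpec(128, 128), nFrames = 5,
                        seed = 8)
  fr <- renderFrame(sim, 5)
  bg <- list(image = arenaBackground(sim@arena))
  b1 <- segmentFrame(fr, bg, 0.2, 5)
  expect_false(anyDuplicated(unlist(b1$mask)) > 0)
  expect_true(all(vapply(seq_len(nrow(b1)), function(i)
    length(b1$mask[[i]]) == b1$area[i], logical(1))))
  areas <- vapply(c(0.2, 0.35, 0.5, 0.65),
                  function(th) sum(segmentFrame(fr, bg, th, 1)$area),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("mask orientation follows the principal axis", {
  h <- 40
  rect <- function(x0, x1, y0, y1)
    as.vector(outer((x0:x1) * h, (y0:y1) + 1L, "+"))
  expect_equal(blobOrientation(rect(5, 24, 10, 13), h), 0)
  expect_equal(blobOrientation(rect(10, 13, 5, 24), h), pi / 2)
  expect_true(is.na(blobOrientation(rect(5, 5, 5, 5), h)))
})

test_that("crops are fixed-size and padded at frame edges", {
  fr <- flatBG(40, 40, 0.8)
  fr[18:22, 18:22, ] <- 0.1
  crop <- extractCrop(fr, 20, 20, 16)
  expect_equal(dim(crop), c(16, 16, 3))
  edge <- extractCrop(fr, 1, 1, 16, bg = flatBG(40, 40, 0.8))
  expect_equal(dim(edge), c(16, 16, 3))
  expect_equal(edge[1, 1, 1], 0.8)   # padded corner
})
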