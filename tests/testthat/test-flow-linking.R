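sq <- function(h, w, ys, xs, v = 0.1, bgv = 0.9) {
  f <- array(bgv, c(h, w, 3)); f[ys, xs, ] <- v; f
}

test_that("flow is zero on identical frames and recovers a pure translation", {
  f1 <- sq(60, 60, 20:30, 10:20)
  fl0 <- estimateFlow(f1, f1, c(5, 15, 30, 35))
  expect_true(all(fl0$dx == 0) && all(fl0$dy == 0))

  f2 <- sq(60, 60, 20:30, 15:25)
  fl <- estimateFlow(f1, f2, c(5, 12, 30, 38))
  rows <- (20:30) - fl$bbox[2]; cols <- (10:20) - fl$bbox[1]
  expect_lt(abs(mean(fl$dx[rows, cols]) - 5), 1)
  expect_lt(abs(mean(fl$dy[rows, cols])), 1)
  expect_error(estimateFlow(f1, f2, c(10, 10, 10, 12)), "empty")
})

test_that("flow on pure noise returns a field without crashing", {
  set.seed(1)
  n1 <- array(runif(40 * 40 * 3), c(40, 40, 3))
  n2 <- array(runif(40 * 40 * 3), c(40, 40, 3))
  fl <- estimateFlow(n1, n2, c(5, 5, 35, 35))
  expect_equal(dim(fl$dx), c(30, 30))
})

test_that("stationary blobs link 1-1 with full support; vanished blobs do not link", {
  bg <- list(image = sq(50, 50, 1, 1, v = 0.9))
  fA <- sq(50, 50, 10:18, 10:18)
  bA <- segmentFrame(fA, bg, 0.3, 5)
  links <- linkBlobs(bA, bA, fA, fA, c(50, 50))
  expect_equal(nrow(links), 1)
  expect_equal(links$support, 1)
  # blob disappears: no links
  fEmpty <- sq(50, 50, 1, 1, v = 0.9)
  bE <- segmentFrame(fEmpty, bg, 0.3, 5)
  expect_equal(nrow(linkBlobs(bA, bE, fA, fEmpty, c(50, 50))), 0)
})

test_that("a merge event yields two links into the merged blob", {
  bg <- list(image = sq(50, 70, 1, 1, v = 0.9))
  fPrev <- sq(50, 70, 20:28, 10:18)
  fPrev[20:28, 26:34, ] <- 0.1
  fCur <- sq(50, 70, 20:28, 14:30)
  bP <- segmentFrame(fPrev, bg, 0.3, 5)
  bC <- segmentFrame(fCur, bg, 0.3, 5)
  expect_equal(nrow(bP), 2)
  expect_equal(nrow(bC), 1)
  links <- linkBlobs(bP, bC, fPrev, fCur, c(50, 70))
  expect_equal(nrow(links), 2)
  expect_setequal(links$prev, 1:2)
  expect_true(all(links$cur == 1))
})

test_that("tracklet update rules open, close, extend and register edges", {
  # exclusive pair extends
  upd <- updateTracklets(data.frame(prev = 1, cur = 1, support = 1),
                         prevTracklets = 5L, nCur = 1, nextId = 7L)
  expect_equal(upd$curTracklets, 5L)
  expect_equal(nrow(upd$edges), 0)
  expect_length(upd$closed, 0)

  # unlinked current blob opens; unlinked previous blob closes
  upd2 <- updateTracklets(data.frame(prev = integer(0), cur = integer(0),
                                     support = numeric(0)),
                          prevTracklets = c(3L, 4L), nCur = 1, nextId = 7L)
  expect_equal(upd2$curTracklets, 7L)
  expect_setequal(upd2$closed, c(3L, 4L))
  expect_equal(upd2$opened, 7L)

  # merge: both previous tracklets close, merged blob opens with two edges
  upd3 <- updateTracklets(data.frame(prev = c(1, 2), cur = c(1, 1),
                                     support = c(1, 1)),
                          prevTracklets = c(3L, 4L), nCur = 1, nextId = 7L)
  expect_equal(upd3$curTracklets, 7L)
  expect_setequal(upd3$closed, c(3L, 4L))
  expect_equal(sort(upd3$edges$from), c(3L, 4L))
  expect_equal(upd3$edges$to, c(7L, 7L))

  # split: one previous closes, two open, two edges
  upd4 <- updateTracklets(data.frame(prev = c(1, 1), cur = c(1, 2),
                                     support = c(0.5, 0.5)),
                          prevTracklets = 9L, nCur = 2, nextId = 10L)
  expect_equal(upd4$curTracklets, c(10L, 11L))
  expect_equal(upd4$closed, 9L)
  expect_equal(upd4$edges, data.frame(from = c(9L, 9L), to = c(10L, 11L)))

  # a link from a blob with no open tracklet is an internal error
  expect_error(updateTracklets(data.frame(prev = 1, cur = 1, support = 1),
                               prevTracklets = NA_integer_, nCur = 1,
                               nextId = 2L),
               "internal consistency")
})
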