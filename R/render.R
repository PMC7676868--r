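# Frame rendering: agents drawn as dark elongated bodies (capsules) with a
# darker head disc (breaks the head/tail symmetry the classifier and the
# orientation disambiguation rely on) and 1-3 small colored tag discs along
# the body axis, on a light background with a gentle horizontal gradient.
# Additive Gaussian pixel noise is applied per frame, seeded per frame so
# any frame can be rendered independently (videos are never held in memory).

.BODY_VAL <- 0.13
.HEAD_VAL <- 0.05

#' Background image of an arena
#'
#' @param arena from [arenaSpec()].
#' @return height x width x 3 array in [0, 1].
#' @export
arenaBackground <- function(arena) {
  h <- arena$height; w <- arena$width
  grad <- matrix(rep(0.84 + 0.08 * (seq_len(w) - 1) / max(w - 1, 1),
                     each = h), h, w)
  array(rep(grad, 3L), c(h, w, 3L))
}

# tag center offsets along the body axis, in units of the capsule
# half-length, ordered head to tail
.tagOffsets <- function(nTags) {
  switch(nTags, c(0.1), c(0.5, -0.55), c(0.65, 0.0, -0.65))
}

# paint agents onto `frame` (modified copy returned); x/y/heading vectors,
# rows of `agents` matched by position; `order` = drawing order (first =
# bottom layer, later agents overpaint, occluding tags below)
.paintAgents <- function(frame, agents, x, y, heading, order = seq_along(x),
                         hideTags = FALSE) {
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  # work on separate channel planes: avoids copying the full frame for
  # every painted primitive
  R <- frame[, , 1L]; G <- frame[, , 2L]; B <- frame[, , 3L]
  for (i in order) {
    L <- agents$bodyLength[i]; bw <- agents$bodyWidth[i]
    rw <- bw / 2; hl <- max(L / 2 - rw, 0.5)
    ux <- cos(heading[i]); uy <- sin(heading[i])
    pad <- ceiling(L / 2 + 2)
    x0 <- max(0L, floor(x[i]) - pad); x1 <- min(w - 1L, ceiling(x[i]) + pad)
    y0 <- max(0L, floor(y[i]) - pad); y1 <- min(h - 1L, ceiling(y[i]) + pad)
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    px <- matrix(rep(xs, each = length(ys)), length(ys))
    py <- matrix(rep(ys, length(xs)), length(ys))
    # distance to the body axis segment
    relx <- px - x[i]; rely <- py - y[i]
    tpar <- pmin(pmax((relx * ux + rely * uy) / hl, -1), 1)
    dseg2 <- (relx - tpar * hl * ux)^2 + (rely - tpar * hl * uy)^2
    body <- dseg2 <= rw^2
    hx <- x[i] + hl * ux; hy <- y[i] + hl * uy
    headm <- (px - hx)^2 + (py - hy)^2 <= (0.8 * rw)^2
    sel <- function(m) {
      idx <- which(m)
      (py[idx] + 1L) + (px[idx]) * h
    }
    bidx <- sel(body); hidx <- sel(headm)
    R[bidx] <- .BODY_VAL; G[bidx] <- .BODY_VAL; B[bidx] <- .BODY_VAL
    R[hidx] <- .HEAD_VAL; G[hidx] <- .HEAD_VAL; B[hidx] <- .HEAD_VAL
    if (!hideTags) {
      offs <- .tagOffsets(agents$nTags[i])
      rt <- max(1.6, bw * 0.30)
      cols <- agents$tagColors[[i]]
      for (k in seq_along(cols)) {
        tx <- x[i] + offs[k] * hl * ux; ty <- y[i] + offs[k] * hl * uy
        tagm <- (px - tx)^2 + (py - ty)^2 <= rt^2
        idx <- sel(tagm)
        if (!length(idx)) next
        R[idx] <- cols[[k]][1L]; G[idx] <- cols[[k]][2L]
        B[idx] <- cols[[k]][3L]
      }
    }
  }
  frame[, , 1L] <- R; frame[, , 2L] <- G; frame[, , 3L] <- B
  frame
}

#' Render one simulated frame
#'
#' Deterministic given `(sim, t, noiseSd, seed)`: the additive Gaussian
#' noise stream is seeded per frame, so frames can be rendered lazily and
#' out of order.
#'
#' @param sim an \linkS4class{ArenaSimulation}.
#' @param t frame index (1-based).
#' @param noiseSd standard deviation of additive pixel noise (0 disables).
#' @param seed noise seed; defaults to the simulation seed.
#' @param hideTags render bodies without tags (used to synthesize
#'   "unidentifiable" training crops).
#' @return height x width x 3 array in [0, 1].
#' @export
renderFrame <- function(sim, t, noiseSd = 0.02, seed = sim@seed,
                        hideTags = FALSE) {
  stopifnot(methods::is(sim, "ArenaSimulation"))
  if (t < 1L || t > sim@nFrames) stop("frame index out of range")
  g <- sim@gt[sim@gt$frame == t, , drop = FALSE]
  g <- g[g$present, , drop = FALSE]
  frame <- arenaBackground(sim@arena)
  if (nrow(g)) {
    rows <- match(g$id, sim@agents$id)
    frame <- .paintAgents(frame, sim@agents[rows, , drop = FALSE],
                          g$x, g$y, g$heading,
                          order = order(g$drawOrder), hideTags = hideTags)
  }
  if (noiseSd > 0) {
    frame <- .withSeed(.subSeed(seed, t), {
      frame + array(rnorm(length(frame), 0, noiseSd), dim(frame))
    })
  }
  frame[frame < 0] <- 0; frame[frame > 1] <- 1
  frame
}

#' Lazy frame accessors
#'
#' `frameSource` wraps a simulation as a `function(t)` returning rendered
#' frames; `frameSourceFromDir` wraps a fixture directory of numbered PNGs.
#' Both carry attributes `nFrames` and `frameDim` (height, width).
#'
#' @inheritParams renderFrame
#' @return a function of the frame index.
#' @export
frameSource <- function(sim, noiseSd = 0.02, seed = sim@seed) {
  f <- function(t) renderFrame(sim, t, noiseSd = noiseSd, seed = seed)
  attr(f, "nFrames") <- sim@nFrames
  attr(f, "frameDim") <- c(sim@arena$height, sim@arena$width)
  f
}

#' @rdname frameSource
#' @param dir fixture directory containing `frames/%06d.png`.
#' @export
frameSourceFromDir <- function(dir) {
  files <- sort(list.files(file.path(dir, "frames"), pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG frames under ", file.path(dir, "frames"))
  first <- .readFramePNG(files[[1L]])
  f <- function(t) .readFramePNG(files[[t]])
  attr(f, "nFrames") <- length(files)
  attr(f, "frameDim") <- dim(first)[1:2]
  f
}

.readFramePNG <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
}

.writeFramePNG <- function(frame, path) {
  img <- EBImage::Image(aperm(frame, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path)
}

#' Render a batch of frames into memory
#'
#' Convenience for short clips and tests; long videos should go through
#' [frameSource()].
#'
#' @inheritParams renderFrame
#' @param frames frame indices (default all).
#' @return list of height x width x 3 arrays.
#' @export
renderFrames <- function(sim, frames = seq_len(sim@nFrames), noiseSd = 0.02,
                         seed = sim@seed) {
  lapply(frames, renderFrame, sim = sim, noiseSd = noiseSd, seed = seed)
}

#' Write a simulation to disk as a tracking fixture
#'
#' Layout: `frames/%06d.png`, `gt.csv` (frame, id, x, y, heading, present,
#' aggregate) and `spec.json` (agents, arena size, seeds, parameters).
#'
#' @inheritParams renderFrame
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeFixture <- function(sim, path, noiseSd = 0.02, seed = sim@seed) {
  dir.create(file.path(path, "frames"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create fixture directory ", path)
  for (t in seq_len(sim@nFrames))
    .writeFramePNG(renderFrame(sim, t, noiseSd = noiseSd, seed = seed),
                   file.path(path, "frames", sprintf("%06d.png", t)))
  gt <- sim@gt[, c("frame", "id", "x", "y", "heading", "present", "aggregate")]
  write.csv(gt, file.path(path, "gt.csv"), row.names = FALSE)
  spec <- list(
    agents = lapply(seq_len(nrow(sim@agents)), function(i) list(
      id = sim@agents$id[i], tagColors = sim@agents$tagColors[[i]],
      bodyLength = sim@agents$bodyLength[i], speed = sim@agents$speed[i])),
    arena = list(width = sim@arena$width, height = sim@arena$height,
                 openBoundary = sim@arena$openBoundary),
    nFrames = sim@nFrames, motion = sim@motion, seed = sim@seed,
    noiseSd = noiseSd, noiseSeed = seed)
  jsonlite::write_json(spec, file.path(path, "spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fixture's ground truth table
#'
#' @param path fixture directory written by [writeFixture()].
#' @return data.frame as written in `gt.csv`.
#' @export
readFixtureGT <- function(path) {
  read.csv(file.path(path, "gt.csv"), stringsAsFactors = FALSE)
}
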