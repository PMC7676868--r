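# Dense block-matching optical flow.
#
# For every pixel of a region the integer displacement minimizing the
# locally summed squared difference between the previous and current frame
# is selected (patch SSD via integral images). A small displacement-norm
# penalty makes the zero shift win ties, so identical frames give a zero
# field. Flow is only ever run on the small regions around ambiguous
# linking events, which keeps the cost negligible compared to running it
# on full frames.

#' Dense displacement field between two frames over a region
#'
#' @param framePrev,frameCur frames as height x width x 3 arrays (or
#'   grayscale matrices).
#' @param bbox region c(x0, y0, x1, y1), 0-based half-open, covering the
#'   blobs whose linking is ambiguous (with margin added internally).
#' @param searchPx maximum displacement searched in each direction.
#' @param patchR half-width of the matching patch.
#' @return list with matrices `dx`, `dy` (displacement per region pixel)
#'   and the clipped region `bbox`.
#' @export
estimateFlow <- function(framePrev, frameCur, bbox, searchPx = 8,
                         patchR = 4, stride = 1L) {
  gPrev <- if (length(dim(framePrev)) == 3L) .luminance(framePrev) else framePrev
  gCur <- if (length(dim(frameCur)) == 3L) .luminance(frameCur) else frameCur
  if (!all(dim(gPrev) == dim(gCur))) stop("frame dimensions differ")
  h <- nrow(gPrev); w <- ncol(gPrev)
  x0 <- max(0L, as.integer(bbox[1L])); y0 <- max(0L, as.integer(bbox[2L]))
  x1 <- min(w, as.integer(bbox[3L])); y1 <- min(h, as.integer(bbox[4L]))
  if (x1 <= x0 || y1 <= y0) stop("empty flow region")
  hr <- y1 - y0; wr <- x1 - x0
  P <- gPrev[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]

  shifts <- expand.grid(dx = -searchPx:searchPx, dy = -searchPx:searchPx)
  ord <- order(shifts$dx^2 + shifts$dy^2, shifts$dy, shifts$dx)
  shifts <- shifts[ord, , drop = FALSE]

  stride <- max(1L, as.integer(stride))
  ry <- seq(1L, hr, by = stride); rx <- seq(1L, wr, by = stride)
  Ps <- P[ry, rx, drop = FALSE]
  pr <- max(1L, patchR %/% stride)
  best <- matrix(Inf, length(ry), length(rx))
  bdx <- matrix(0L, length(ry), length(rx)); bdy <- bdx
  padv <- median(gCur[c(1L, h), c(1L, w)])
  for (s in seq_len(nrow(shifts))) {
    dx <- shifts$dx[s]; dy <- shifts$dy[s]
    C <- matrix(padv, hr, wr)
    ys <- (y0 + dy):(y1 - 1L + dy); xs <- (x0 + dx):(x1 - 1L + dx)
    oky <- ys >= 0L & ys <= h - 1L; okx <- xs >= 0L & xs <= w - 1L
    if (any(oky) && any(okx))
      C[which(oky), which(okx)] <- gCur[ys[oky] + 1L, xs[okx] + 1L]
    cost <- .boxSum((Ps - C[ry, rx, drop = FALSE])^2, pr) +
      1e-4 * (dx * dx + dy * dy)
    better <- cost < best
    if (any(better)) {
      best[better] <- cost[better]
      bdx[better] <- dx; bdy[better] <- dy
    }
  }
  if (stride > 1L) {
    # nearest-sample upsampling back to the full region grid
    iy <- pmin(((seq_len(hr) - 1L) %/% stride) + 1L, length(ry))
    ix <- pmin(((seq_len(wr) - 1L) %/% stride) + 1L, length(rx))
    bdx <- bdx[iy, ix, drop = FALSE]; bdy <- bdy[iy, ix, drop = FALSE]
  }
  list(dx = bdx, dy = bdy, bbox = c(x0, y0, x1, y1))
}
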