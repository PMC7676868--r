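# Internal helpers shared across modules.
#
# Conventions used repo-wide: pixel coordinates are 0-based, x rightward,
# y downward; a frame is a numeric array [height, width, 3] with values in
# [0, 1]; a pixel (x, y) maps to array element [y + 1, x + 1, ]; blob masks
# are integer vectors of linear indices into the height x width plane.

#' @importFrom stats runif rnorm median quantile setNames qbeta
#' @importFrom utils head tail write.csv read.csv
NULL

.wrapAngle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

.wrapOrient <- function(a) {
  # wrap to [0, pi)
  a %% pi
}

# smallest absolute difference between two orientations mod pi
.orientDiff <- function(a, b) {
  d <- abs(.wrapOrient(a) - .wrapOrient(b))
  pmin(d, pi - d)
}

# run a block with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# derive a sub-seed from a master seed, kept within 32-bit integer range
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(k)) %% 2147483647L)
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# linear index <-> 0-based (x, y) for a height x width plane
.pxToXY <- function(idx, height) {
  idx0 <- idx - 1L
  cbind(x = idx0 %/% height, y = idx0 %% height)
}

.xyToPx <- function(x, y, height) {
  as.integer(x) * height + as.integer(y) + 1L
}

# columnwise cumulative sums via one vector cumsum (no per-column R loop)
.colCumsum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  v <- cumsum(m)
  if (w > 1L) v <- v - rep(c(0, v[h * seq_len(w - 1L)]), each = h)
  matrix(v, h, w)
}

# local box sums of a matrix with half-width r (integral image)
.boxSum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(0, h + 1L, w + 1L)
  cs[-1L, -1L] <- t(.colCumsum(t(.colCumsum(m))))
  y0 <- pmax(0L, seq_len(h) - r - 1L); y1 <- pmin(h, seq_len(h) + r)
  x0 <- pmax(0L, seq_len(w) - r - 1L); x1 <- pmin(w, seq_len(w) + r)
  cs[y1 + 1L, x1 + 1L, drop = FALSE] - cs[y0 + 1L, x1 + 1L, drop = FALSE] -
    cs[y1 + 1L, x0 + 1L, drop = FALSE] + cs[y0 + 1L, x0 + 1L, drop = FALSE]
}

# grayscale = max over channels (tags are colored, bodies dark: the max
# channel difference captures both against a light background)
.maxChanAbsDiff <- function(frame, bg) {
  pmax(abs(frame[, , 1L] - bg[, , 1L]),
       abs(frame[, , 2L] - bg[, , 2L]),
       abs(frame[, , 3L] - bg[, , 3L]))
}

.luminance <- function(frame) {
  0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
}
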