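# Background estimation and blob segmentation.
#
# Background = per-pixel median over frames sampled uniformly in time
# (robust to transient animals). Foreground = pixels whose max-over-channel
# absolute difference from the background exceeds a fixed threshold,
# restricted to the ROI; blobs are 8-connected components, small components
# discarded. Merged animals are deliberately left unsplit: their
# composition is inferred later on the tracklet graph.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
.label8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(binary))
  nl <- max(lab)
  if (nl >= 2L) {
    h <- nrow(lab); w <- ncol(lab)
    a <- lab[-h, -w]; b <- lab[-1L, -1L]   # NW-SE diagonal pairs
    c1 <- lab[-h, -1L]; d1 <- lab[-1L, -w] # NE-SW diagonal pairs
    pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                   cbind(c1[c1 > 0 & d1 > 0 & c1 != d1],
                         d1[c1 > 0 & d1 > 0 & c1 != d1]))
    if (nrow(pairs)) {
      parent <- seq_len(nl)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
        if (ri != rj) parent[ri] <- rj
      }
      roots <- vapply(seq_len(nl), find, integer(1))
      remap <- match(roots, unique(roots))
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  lab
}

#' Estimate the static background of a frame sequence
#'
#' Per-pixel median over `nSamples` frames sampled uniformly in time. If
#' the sequence is shorter than `nSamples`, all frames are used.
#'
#' @param frames a list of frames or a [frameSource()] function.
#' @param nSamples number of frames to sample (>= 3).
#' @param nFrames total frame count (required for a frame source without
#'   the `nFrames` attribute).
#' @return list with `image` (height x width x 3 background) and
#'   `nSamples` actually used.
#' @export
estimateBackground <- function(frames, nSamples = 9, nFrames = NULL) {
  .assertScalarNum(nSamples, "nSamples", lower = 3)
  if (is.function(frames)) {
    total <- if (!is.null(nFrames)) nFrames else attr(frames, "nFrames")
    if (is.null(total)) stop("supply 'nFrames' for a frame source")
    getf <- frames
  } else {
    total <- length(frames)
    getf <- function(t) frames[[t]]
  }
  if (total < 1L) stop("no frames to estimate a background from")
  n <- min(as.integer(nSamples), total)
  at <- unique(round(seq(1L, total, length.out = n)))
  stack <- vapply(at, function(t) getf(t),
                  FUN.VALUE = array(0, dim(getf(at[1L]))))
  dm <- dim(stack)
  med <- apply(matrix(stack, ncol = length(at)), 1L, median)
  list(image = array(med, dm[1:3]), nSamples = length(at))
}

#' Segment one frame into animal-containing blobs
#'
#' Connected components (8-connectivity) of
#' `max_channel |frame - background| > threshold` within the ROI, with
#' components smaller than `minArea` discarded. No attempt is made to
#' split blobs containing several touching animals.
#'
#' @param frame height x width x 3 array.
#' @param bg background model from [estimateBackground()] (or a bare array).
#' @param threshold positive difference threshold.
#' @param minArea minimum blob area in pixels.
#' @param roiMask logical height x width matrix, or NULL for full frame.
#' @param cropPx side of the square crop extracted around each centroid
#'   (0 disables crop extraction).
#' @return data.frame with one row per blob: `x`, `y` (centroid, 0-based
#'   float px), `area`, `bbox` (list of c(x0, y0, x1, y1), half-open),
#'   `orient` (principal-axis orientation in [0, pi), NA if degenerate),
#'   `mask` (list of linear pixel indices), `crop` (list of arrays or NULL).
#' @export
segmentFrame <- function(frame, bg, threshold = 0.3, minArea = 16,
                         roiMask = NULL, cropPx = 0) {
  .assertScalarNum(threshold, "threshold", lower = 1e-9)
  bgimg <- if (is.list(bg)) bg$image else bg
  if (!all(dim(frame) == dim(bgimg)))
    stop("frame and background dimensions differ")
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  diffm <- .maxChanAbsDiff(frame, bgimg)
  fg <- diffm > threshold
  if (!is.null(roiMask)) {
    if (!all(dim(roiMask) == c(h, w))) stop("roiMask dimensions differ from frame")
    fg <- fg & roiMask
  }
  if (!any(fg)) return(.emptyBlobs())
  lab <- .label8(fg)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  areas <- tabulate(labs)
  keep <- which(areas >= minArea)
  if (!length(keep)) return(.emptyBlobs())
  out <- lapply(keep, function(k) {
    pix <- idx[labs == k]
    xy <- .pxToXY(pix, h)
    cx <- mean(xy[, "x"]); cy <- mean(xy[, "y"])
    bbox <- c(min(xy[, "x"]), min(xy[, "y"]),
              max(xy[, "x"]) + 1L, max(xy[, "y"]) + 1L)
    list(x = cx, y = cy, area = length(pix), bbox = bbox, mask = pix)
  })
  blobs <- data.frame(
    x = vapply(out, `[[`, numeric(1), "x"),
    y = vapply(out, `[[`, numeric(1), "y"),
    area = vapply(out, `[[`, integer(1), "area"))
  blobs$bbox <- lapply(out, `[[`, "bbox")
  blobs$mask <- lapply(out, `[[`, "mask")
  blobs$orient <- vapply(seq_len(nrow(blobs)), function(i)
    blobOrientation(blobs$mask[[i]], h), numeric(1))
  blobs$crop <- if (cropPx > 0)
    lapply(seq_len(nrow(blobs)), function(i)
      extractCrop(frame, blobs$x[i], blobs$y[i], cropPx, bgimg))
  else vector("list", nrow(blobs))
  blobs
}

.emptyBlobs <- function() {
  b <- data.frame(x = numeric(0), y = numeric(0), area = integer(0))
  b$bbox <- list(); b$mask <- list(); b$orient <- numeric(0); b$crop <- list()
  b
}

#' Principal-axis orientation of a blob mask
#'
#' Orientation of the mask's principal axis from second-order central
#' moments, in [0, pi). Head/tail disambiguation is not attempted here;
#' it is resolved from displacement at trajectory export.
#'
#' @param mask linear pixel indices of the blob.
#' @param height frame height (rows).
#' @return orientation in radians in [0, pi); NA for degenerate masks
#'   (fewer than 3 pixels or isotropic).
#' @export
blobOrientation <- function(mask, height) {
  if (length(mask) < 3L) return(NA_real_)
  xy <- .pxToXY(mask, height)
  x <- xy[, "x"] - mean(xy[, "x"]); y <- xy[, "y"] - mean(xy[, "y"])
  mxx <- mean(x * x); myy <- mean(y * y); mxy <- mean(x * y)
  if (abs(mxy) < 1e-12 && abs(mxx - myy) < 1e-12) return(NA_real_)
  .wrapOrient(0.5 * atan2(2 * mxy, mxx - myy))
}

#' Extract a fixed-size crop around a point
#'
#' Square `cropPx` x `cropPx` patch centered on the (rounded) centroid,
#' padded with the local background color where it leaves the frame.
#'
#' @param frame height x width x 3 array.
#' @param cx,cy center, 0-based pixel coordinates.
#' @param cropPx crop side in pixels.
#' @param bg background array used for padding (NULL pads with the frame
#'   corner color).
#' @return cropPx x cropPx x 3 array.
#' @export
extractCrop <- function(frame, cx, cy, cropPx, bg = NULL) {
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  half <- cropPx %/% 2L
  padv <- if (!is.null(bg)) mean(bg) else mean(frame[1L, 1L, ])
  crop <- array(padv, c(cropPx, cropPx, 3L))
  xs <- (round(cx) - half):(round(cx) - half + cropPx - 1L)
  ys <- (round(cy) - half):(round(cy) - half + cropPx - 1L)
  okx <- xs >= 0L & xs <= w - 1L; oky <- ys >= 0L & ys <= h - 1L
  if (any(okx) && any(oky))
    crop[which(oky), which(okx), ] <- frame[ys[oky] + 1L, xs[okx] + 1L, ]
  crop
}
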