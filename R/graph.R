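# Tracklet bookkeeping and construction of the directed tracklet graph.
#
# Tracklet update rules applied after linking frame t to frame t-1:
#   (i)   a current blob with no link opens a new tracklet;
#   (ii)  a previous blob with no link closes its tracklet;
#   (iii) an exclusively linked pair extends the previous blob's tracklet;
#   (iv)  any blob involved in a >1-link relation closes all linked
#         previous tracklets and opens new tracklets for the current
#         blobs, registering a graph edge earlier -> later per link.

#' Apply the tracklet open/close/extend rules for one frame transition
#'
#' Pure bookkeeping step, exposed for direct testing. Tracklet ids are
#' assigned in order of opening.
#'
#' @param links link table from [linkBlobs()].
#' @param prevTracklets integer vector: open tracklet id of each blob in
#'   frame t - 1.
#' @param nCur number of blobs in frame t.
#' @param nextId next unused tracklet id.
#' @return list: `curTracklets` (tracklet id per current blob), `edges`
#'   (data.frame from/to), `closed` (ids closed at t - 1), `opened`
#'   (ids opened at t), `nextId`.
#' @export
updateTracklets <- function(links, prevTracklets, nCur, nextId) {
  np <- length(prevTracklets)
  if (nrow(links)) {
    if (any(links$prev < 1L | links$prev > np) ||
        any(links$cur < 1L | links$cur > nCur))
      stop("internal consistency failure: link references an unknown blob")
    if (anyNA(prevTracklets[links$prev]))
      stop("internal consistency failure: link from a blob with no open tracklet")
  }
  outdeg <- tabulate(links$prev, nbins = np)
  indeg <- tabulate(links$cur, nbins = max(nCur, 1L))
  curTracklets <- rep(NA_integer_, nCur)
  edges <- data.frame(from = integer(0), to = integer(0))
  extended <- logical(np)

  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      p <- links$prev[r]; c <- links$cur[r]
      if (outdeg[p] == 1L && indeg[c] == 1L) {        # rule (iii)
        curTracklets[c] <- prevTracklets[p]
        extended[p] <- TRUE
      }
    }
  }
  if (nCur > 0L) {
    for (c in which(is.na(curTracklets))) {           # rules (i) and (iv)
      curTracklets[c] <- nextId
      nextId <- nextId + 1L
    }
  }
  if (nrow(links)) {
    amb <- links[!(outdeg[links$prev] == 1L & indeg[links$cur] == 1L), ,
                 drop = FALSE]
    if (nrow(amb))
      edges <- data.frame(from = prevTracklets[amb$prev],
                          to = curTracklets[amb$cur])
  }
  closed <- unique(prevTracklets[!extended & !is.na(prevTracklets)])
  opened <- setdiff(curTracklets, prevTracklets)
  list(curTracklets = curTracklets, edges = unique(edges),
       closed = closed, opened = opened, nextId = nextId)
}

.blobTouchesBoundary <- function(bbox, frameDim, band) {
  bbox[1L] <= band || bbox[2L] <= band ||
    bbox[3L] >= frameDim[2L] - band || bbox[4L] >= frameDim[1L] - band
}

#' Build the tracklet graph from a frame sequence
#'
#' Runs the full segmentation + linking loop over all frames: background
#' estimation, per-frame blob segmentation, optical-flow-assisted linking,
#' and the tracklet update rules, producing a directed acyclic tracklet
#' graph. Optionally classifies each blob on the fly (streaming, so crops
#' never need to be retained for long videos).
#'
#' @param frames a list of frames or a [frameSource()] function.
#' @param threshold segmentation threshold (max-channel absolute
#'   difference from background).
#' @param minArea minimum blob area in pixels.
#' @param roiMask logical region-of-interest mask or NULL.
#' @param openBoundary may animals enter/leave the ROI? Sets per-tracklet
#'   boundary flags used by the propagation solver.
#' @param boundaryBand width in px of the border band where a tracklet
#'   endpoint counts as touching the open boundary.
#' @param supportMin,searchPx,flowStride linking parameters, see
#'   [linkBlobs()].
#' @param bgSamples frames sampled for the background median.
#' @param bg optional precomputed background model.
#' @param refArea reference single-animal area for link support
#'   normalization; by default four times `minArea` (which is itself
#'   conventionally a quarter of the expected single-animal area).
#' @param cropPx store a crop per blob (0 = do not store).
#' @param classifier optional blob classifier (see [oracleClassifier()] /
#'   [trainBlobClassifier()]) applied per frame; per-blob labels and
#'   scores are stored in the blob tables.
#' @param verbose log per-stage counts to stderr.
#' @return a \linkS4class{TrackletGraph}.
#' @export
buildTrackletGraph <- function(frames, threshold = 0.3, minArea = 16,
                               roiMask = NULL, openBoundary = FALSE,
                               boundaryBand = 6, supportMin = 0.25,
                               searchPx = 8, flowStride = 2L, bgSamples = 9,
                               bg = NULL, refArea = 4 * minArea,
                               cropPx = 0, classifier = NULL,
                               verbose = FALSE) {
  if (is.function(frames)) {
    total <- attr(frames, "nFrames")
    if (is.null(total)) stop("frame source lacks an nFrames attribute")
    getf <- frames
  } else {
    total <- length(frames)
    getf <- function(t) frames[[t]]
  }
  if (total < 1L) stop("no frames")
  if (is.null(bg)) bg <- estimateBackground(frames, nSamples = bgSamples,
                                            nFrames = total)
  frameDim <- dim(bg$image)[1:2]

  blobStore <- vector("list", total)
  trkOf <- vector("list", total)      # tracklet id per blob per frame
  edgesAll <- list()
  nextId <- 1L
  prevBlobs <- NULL; prevTrk <- integer(0); prevGray <- NULL
  nBlobsTotal <- 0L

  for (t in seq_len(total)) {
    fr <- getf(t)
    gray <- .luminance(fr)    # flow works on luminance; convert once
    blobs <- segmentFrame(fr, bg, threshold = threshold, minArea = minArea,
                          roiMask = roiMask, cropPx = cropPx)
    if (!is.null(classifier) && nrow(blobs)) {
      pr <- predictBlobs(classifier, blobs, frame = fr, frameIndex = t)
      blobs$blobLabel <- colnames(pr)[max.col(pr, ties.method = "first")]
      blobs$blobScore <- pr[cbind(seq_len(nrow(pr)),
                                  max.col(pr, ties.method = "first"))]
    }
    if (t == 1L) {
      trk <- if (nrow(blobs)) seq_len(nrow(blobs)) else integer(0)
      nextId <- length(trk) + 1L
    } else {
      links <- linkBlobs(prevBlobs, blobs, prevGray, gray, frameDim,
                         supportMin = supportMin, searchPx = searchPx,
                         flowStride = flowStride, refArea = refArea)
      upd <- updateTracklets(links, prevTrk, nrow(blobs), nextId)
      trk <- upd$curTracklets
      nextId <- upd$nextId
      if (nrow(upd$edges)) edgesAll[[length(edgesAll) + 1L]] <- upd$edges
    }
    blobStore[[t]] <- blobs
    trkOf[[t]] <- trk
    nBlobsTotal <- nBlobsTotal + nrow(blobs)
    prevBlobs <- blobs; prevTrk <- trk; prevGray <- gray
    if (verbose && (t %% 200L == 0L || t == total))
      message(sprintf("frame %d/%d: %d blobs, %d tracklets so far",
                      t, total, nrow(blobs), nextId - 1L))
  }

  nT <- nextId - 1L
  edges <- if (length(edgesAll)) unique(do.call(rbind, edgesAll))
           else data.frame(from = integer(0), to = integer(0))

  # assemble per-tracklet blob tables in one pass
  frameV <- integer(nBlobsTotal); trkV <- integer(nBlobsTotal)
  rowV <- integer(nBlobsTotal)
  k <- 0L
  for (t in seq_len(total)) {
    nb <- nrow(blobStore[[t]])
    if (!nb) next
    idx <- (k + 1L):(k + nb)
    frameV[idx] <- t; trkV[idx] <- trkOf[[t]]; rowV[idx] <- seq_len(nb)
    k <- k + nb
  }
  ord <- order(trkV, frameV)
  frameV <- frameV[ord]; rowV <- rowV[ord]; trkV <- trkV[ord]
  bounds <- c(0L, cumsum(tabulate(trkV, nbins = nT)))

  hasCls <- !is.null(classifier)
  blobsPer <- vector("list", nT)
  start <- integer(nT); end <- integer(nT)
  startsOpen <- logical(nT); endsOpen <- logical(nT)
  for (i in seq_len(max(nT, 0L))) {
    sel <- if (bounds[i + 1L] > bounds[i]) (bounds[i] + 1L):bounds[i + 1L]
           else integer(0)
    fr <- frameV[sel]; rw <- rowV[sel]
    b <- do.call(rbind, lapply(seq_along(sel), function(j)
      blobStore[[fr[j]]][rw[j], c("x", "y", "area", "orient"), drop = FALSE]))
    rownames(b) <- NULL
    b <- cbind(frame = fr, b)
    b$mask <- lapply(seq_along(sel), function(j)
      blobStore[[fr[j]]]$mask[[rw[j]]])
    b$crop <- lapply(seq_along(sel), function(j)
      blobStore[[fr[j]]]$crop[[rw[j]]])
    if (hasCls) {
      b$blobLabel <- vapply(seq_along(sel), function(j)
        blobStore[[fr[j]]]$blobLabel[rw[j]], character(1))
      b$blobScore <- vapply(seq_along(sel), function(j)
        blobStore[[fr[j]]]$blobScore[rw[j]], numeric(1))
    }
    blobsPer[[i]] <- b
    start[i] <- fr[1L]; end[i] <- fr[length(sel)]
    if (openBoundary) {
      bb1 <- blobStore[[fr[1L]]]$bbox[[rw[1L]]]
      bb2 <- blobStore[[fr[length(sel)]]]$bbox[[rw[length(sel)]]]
      startsOpen[i] <- .blobTouchesBoundary(bb1, frameDim, boundaryBand)
      endsOpen[i] <- .blobTouchesBoundary(bb2, frameDim, boundaryBand)
    }
  }

  nodes <- data.frame(tracklet = seq_len(nT), start = start, end = end,
                      nBlobs = diff(bounds), kind = rep("unknown", nT),
                      label = rep(NA_character_, nT),
                      confidence = rep(NA_real_, nT),
                      startsOpen = startsOpen, endsOpen = endsOpen,
                      stringsAsFactors = FALSE)
  methods::new("TrackletGraph", nodes = nodes, edges = edges,
               blobs = blobsPer, nFrames = as.integer(total),
               frameDim = as.integer(frameDim))
}

#' Serialize / read a tracklet graph as CSV tables
#'
#' Writes `nodes.csv`, `edges.csv` and a per-blob `blobs.csv` (centroid
#' table; masks and crops are not serialized). All ASCII, bit-stable given
#' identical input.
#'
#' @param graph a \linkS4class{TrackletGraph}.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeGraph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(trackletNodes(graph), file.path(dir, "nodes.csv"),
            row.names = FALSE)
  write.csv(trackletEdges(graph), file.path(dir, "edges.csv"),
            row.names = FALSE)
  bl <- do.call(rbind, lapply(seq_len(nTracklets(graph)), function(i) {
    b <- trackletBlobs(graph)[[i]]
    data.frame(tracklet = i, frame = b$frame, x = b$x, y = b$y,
               area = b$area, orient = b$orient)
  }))
  write.csv(bl, file.path(dir, "blobs.csv"), row.names = FALSE)
  invisible(dir)
}
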