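# Blob and tracklet classification.
#
# The classifier is a plug-in: anything implementing predictBlobs() that
# maps blobs of one frame to a probability row over the class list
# c(IDs..., "multi", "unknown") can drive the pipeline. Two implementations
# ship with the package: a ground-truth oracle (optionally corrupted with a
# stated error rate) used for testing and validation, and a trainable
# single-hidden-layer neural network over orientation-normalized color
# features of the blob crop.

#' Predict class probabilities for the blobs of one frame
#'
#' @param model a blob classifier (see [oracleClassifier()],
#'   [trainBlobClassifier()]).
#' @param blobs blob table from [segmentFrame()].
#' @param frame the frame array (needed by image-based classifiers when
#'   the blob table carries no stored crops).
#' @param frameIndex 1-based frame index.
#' @return matrix nBlobs x nClasses of probabilities summing to 1 per row,
#'   with class names as colnames.
#' @export
predictBlobs <- function(model, blobs, frame = NULL, frameIndex = NA_integer_)
  UseMethod("predictBlobs")

#' Classes recognized by a blob classifier
#' @param model a blob classifier.
#' @return character vector: ID labels, then "multi", then "unknown".
#' @export
classifierClasses <- function(model) model$classes

#' Ground-truth oracle blob classifier
#'
#' Labels each blob from the simulation ground truth: the ID if exactly
#' one agent's true centroid falls inside the (slightly dilated) blob mask,
#' "multi" if several do, "unknown" if none. With `corruption > 0`, each
#' single-ID label is replaced by a uniformly drawn wrong ID with that
#' probability (deterministically, keyed on frame and blob), emulating a
#' classifier with a stated error rate.
#'
#' @param sim the \linkS4class{ArenaSimulation} that produced the video.
#' @param corruption error rate in [0, 1].
#' @param seed seed for the corruption stream.
#' @return an object of class `c("oracleBlobClassifier", "blobClassifier")`.
#' @export
oracleClassifier <- function(sim, corruption = 0, seed = 1) {
  stopifnot(methods::is(sim, "ArenaSimulation"))
  .assertScalarNum(corruption, "corruption", lower = 0, upper = 1)
  structure(list(classes = c(sim@agents$id, "multi", "unknown"),
                 gt = sim@gt, ids = sim@agents$id,
                 frameDim = c(sim@arena$height, sim@arena$width),
                 corruption = corruption, seed = as.integer(seed)),
            class = c("oracleBlobClassifier", "blobClassifier"))
}

#' @export
predictBlobs.oracleBlobClassifier <- function(model, blobs, frame = NULL,
                                              frameIndex = NA_integer_) {
  if (is.na(frameIndex)) stop("the oracle classifier needs the frame index")
  h <- model$frameDim[1L]; w <- model$frameDim[2L]
  g <- model$gt[model$gt$frame == frameIndex & model$gt$present, ,
                drop = FALSE]
  cls <- model$classes
  pr <- matrix(0, nrow(blobs), length(cls), dimnames = list(NULL, cls))
  lab <- .labelImage(blobs, c(h, w))
  # blob membership of each true agent: label under the (rounded) true
  # centroid, falling back to the 8-neighborhood (1 px dilation)
  blobOf <- if (nrow(g))
    .labelAt(lab, as.integer(round(g$x)), as.integer(round(g$y)), h, w)
  else integer(0)
  for (i in seq_len(nrow(blobs))) {
    members <- g$id[blobOf == i]
    labi <- if (length(members) == 0L) "unknown"
            else if (length(members) > 1L) "multi"
            else members
    if (labi %in% model$ids && model$corruption > 0) {
      u <- .withSeed(.subSeed(model$seed, frameIndex * 10007L + i), runif(2))
      if (u[1L] < model$corruption) {
        others <- setdiff(model$ids, labi)
        labi <- others[1L + floor(u[2L] * length(others))]
      }
    }
    pr[i, labi] <- 1
  }
  pr
}

# ---- trainable classifier ------------------------------------------------

# orientation-normalized color features of a crop: foreground pixels are
# projected on the principal axis (head end, recognizable by the darker
# head disc, mapped to the positive side), split into axial bins, and
# summarized by per-bin mean RGB of tag-colored pixels plus shape stats.
.cropFeatures <- function(crop, nBins = 6L) {
  h <- nrow(crop)
  bgv <- median(crop[c(1:2, h - 1, h), c(1:2, h - 1, h), ])
  dif <- pmax(abs(crop[, , 1] - bgv), abs(crop[, , 2] - bgv),
              abs(crop[, , 3] - bgv))
  fg <- which(dif > 0.25)
  nf <- length(fg)
  empty <- c(rep(0, nBins * 4L), 0, 0, 0)
  if (nf < 5L) return(empty)
  xy <- .pxToXY(fg, h)
  x <- xy[, "x"] - mean(xy[, "x"]); y <- xy[, "y"] - mean(xy[, "y"])
  mxx <- mean(x * x); myy <- mean(y * y); mxy <- mean(x * y)
  ang <- 0.5 * atan2(2 * mxy, mxx - myy)
  s <- x * cos(ang) + y * sin(ang)                 # axial coordinate
  lum <- (crop[, , 1] + crop[, , 2] + crop[, , 3]) / 3
  lumf <- lum[fg]
  # the head disc is near-black, much darker than body or tags: flip the
  # axis so the side holding the darkest pixels (the head) is positive
  dark <- lumf < 0.09
  flip <- if (sum(dark) >= 3) sum(s[dark] > 0) < sum(s[dark] < 0)
          else mean(lumf[s > 0]) > mean(lumf[s < 0])
  if (isTRUE(flip)) s <- -s
  smax <- max(abs(s), 1)
  sn <- s / smax
  bin <- pmin(pmax(ceiling((sn + 1) / 2 * nBins), 1L), nBins)
  sat <- apply(cbind(crop[, , 1][fg], crop[, , 2][fg], crop[, , 3][fg]),
               1L, function(v) max(v) - min(v))
  bright <- pmax(crop[, , 1][fg], crop[, , 2][fg], crop[, , 3][fg])
  tagpx <- sat > 0.25 | (bright > 0.6 & lumf > 0.5)  # colored or white tags
  feats <- numeric(nBins * 4L)
  for (b in seq_len(nBins)) {
    inb <- bin == b
    tb <- inb & tagpx
    if (any(tb)) {
      feats[(b - 1L) * 4L + 1:3] <- c(mean(crop[, , 1][fg][tb]),
                                      mean(crop[, , 2][fg][tb]),
                                      mean(crop[, , 3][fg][tb]))
      feats[(b - 1L) * 4L + 4L] <- sum(tb) / nf
    }
  }
  ecc <- sqrt(max(mxx, myy) / max(min(mxx, myy), 1e-6))
  c(feats, nf / (h * h), min(ecc, 10) / 10, sum(tagpx) / nf)
}

#' Render a labeled example database of blob crops
#'
#' Synthesizes training material for the blob classifier: single-agent
#' crops at random headings for each ID, merged two-agent crops labeled
#' "multi", and tag-hidden crops labeled "unknown".
#'
#' @param agents agent roster (see [colonyAgents()]).
#' @param nPerClass examples per ID (and per ambiguous class, scaled x2).
#' @param cropPx crop side in pixels.
#' @param noiseSd additive noise level.
#' @param seed RNG seed.
#' @return data.frame with columns `label` and list column `crop`.
#' @export
renderExampleCrops <- function(agents, nPerClass = 10, cropPx = 48,
                               noiseSd = 0.02, seed = 1) {
  n <- nrow(agents)
  canvas <- arenaSpec(cropPx + 24L, cropPx + 24L)
  cx <- (canvas$width - 1) / 2; cy <- (canvas$height - 1) / 2
  bgc <- arenaBackground(canvas)
  .withSeed(seed, {
    out <- list(); labs <- character(0)
    paintOne <- function(i, hideTags, dx = 0, dy = 0, headAng = NULL) {
      ang <- if (is.null(headAng)) runif(1, -pi, pi) else headAng
      f <- .paintAgents(bgc, agents[i, , drop = FALSE], cx + dx, cy + dy,
                        ang, hideTags = hideTags)
      f
    }
    addNoise <- function(f) {
      if (noiseSd > 0) f <- f + array(rnorm(length(f), 0, noiseSd), dim(f))
      f[f < 0] <- 0; f[f > 1] <- 1
      f
    }
    for (i in seq_len(n)) for (k in seq_len(nPerClass)) {
      f <- addNoise(paintOne(i, FALSE))
      out[[length(out) + 1L]] <- extractCrop(f, cx, cy, cropPx)
      labs <- c(labs, agents$id[i])
    }
    for (k in seq_len(2L * nPerClass)) {
      i <- 1L + (k - 1L) %% n
      f <- addNoise(paintOne(i, TRUE))
      out[[length(out) + 1L]] <- extractCrop(f, cx, cy, cropPx)
      labs <- c(labs, "unknown")
    }
    for (k in seq_len(2L * nPerClass)) {
      i <- 1L + (k - 1L) %% n
      j <- 1L + (k + floor(n / 2)) %% n
      off <- 0.75 * agents$bodyLength[i]
      ang <- runif(1, -pi, pi)
      f <- .paintAgents(bgc, agents[c(i, j), , drop = FALSE],
                        c(cx - off * cos(ang) / 2, cx + off * cos(ang) / 2),
                        c(cy - off * sin(ang) / 2, cy + off * sin(ang) / 2),
                        runif(2, -pi, pi))
      f <- addNoise(f)
      out[[length(out) + 1L]] <- extractCrop(f, cx, cy, cropPx)
      labs <- c(labs, "multi")
    }
    res <- data.frame(label = labs, stringsAsFactors = FALSE)
    res$crop <- out
    res
  })
}

#' Train the default blob classifier
#'
#' A single-hidden-layer neural network (softmax output) over
#' orientation-normalized color/shape features of the crop. Deterministic
#' given `seed`.
#'
#' @param examples data.frame with `label` and list column `crop`
#'   (see [renderExampleCrops()]); must contain every ID plus the
#'   "unknown" and "multi" classes.
#' @param ids character vector of all ID labels the colony uses.
#' @param hidden hidden units.
#' @param maxit,decay nnet training parameters.
#' @param cropPx crop side expected at prediction time.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `c("nnetBlobClassifier", "blobClassifier")`.
#' @export
trainBlobClassifier <- function(examples, ids, hidden = 16, maxit = 400,
                                decay = 5e-4, cropPx = 48, seed = 1) {
  classes <- c(ids, "multi", "unknown")
  missing <- setdiff(classes, unique(examples$label))
  if (length(missing))
    stop("missing classes in the training set: ",
         paste(missing, collapse = ", "))
  X <- t(vapply(examples$crop, .cropFeatures,
                numeric(length(.cropFeatures(examples$crop[[1L]])))))
  y <- factor(examples$label, levels = classes)
  ctr <- colMeans(X); scl <- pmax(apply(X, 2L, stats::sd), 1e-6)
  Xs <- scale(X, ctr, scl)
  fit <- .withSeed(seed,
    nnet::nnet(Xs, nnet::class.ind(y), size = hidden, softmax = TRUE,
               maxit = maxit, decay = decay, MaxNWts = 50000, trace = FALSE))
  structure(list(classes = classes, fit = fit, center = ctr, scale = scl,
                 cropPx = as.integer(cropPx)),
            class = c("nnetBlobClassifier", "blobClassifier"))
}

#' @export
predictBlobs.nnetBlobClassifier <- function(model, blobs, frame = NULL,
                                            frameIndex = NA_integer_) {
  crops <- blobs$crop
  needs <- vapply(crops, is.null, logical(1))
  if (any(needs)) {
    if (is.null(frame))
      stop("crops are not stored and no frame was supplied")
    crops[needs] <- lapply(which(needs), function(i)
      extractCrop(frame, blobs$x[i], blobs$y[i], model$cropPx))
  }
  X <- t(vapply(crops, .cropFeatures,
                numeric(length(model$center))))
  Xs <- scale(X, model$center, model$scale)
  pr <- stats::predict(model$fit, Xs)
  pr <- matrix(pr, nrow = nrow(blobs), dimnames = list(NULL, model$classes))
  pr / pmax(rowSums(pr), 1e-12)
}

#' Classify every blob of a built graph
#'
#' Adds `blobLabel` and `blobScore` columns to each tracklet's blob table.
#' Image-based classifiers re-extract crops from `frames` when the graph
#' stored none; the oracle works from masks alone.
#'
#' @param graph a \linkS4class{TrackletGraph}.
#' @param model a blob classifier.
#' @param frames optional frame list or [frameSource()].
#' @return the graph with per-blob classifications attached.
#' @export
classifyGraphBlobs <- function(graph, model, frames = NULL) {
  getf <- if (is.function(frames)) frames
          else if (is.list(frames)) function(t) frames[[t]] else NULL
  bl <- graph@blobs
  # group blob references by frame so each frame is touched once
  refs <- do.call(rbind, lapply(seq_along(bl), function(i)
    if (nrow(bl[[i]])) data.frame(trk = i, row = seq_len(nrow(bl[[i]])),
                                  frame = bl[[i]]$frame)))
  if (is.null(refs)) return(graph)
  for (i in seq_along(bl)) {
    bl[[i]]$blobLabel <- rep(NA_character_, nrow(bl[[i]]))
    bl[[i]]$blobScore <- rep(NA_real_, nrow(bl[[i]]))
  }
  for (t in unique(refs$frame)) {
    sub <- refs[refs$frame == t, , drop = FALSE]
    blobs <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r)
      bl[[sub$trk[r]]][sub$row[r], , drop = FALSE]))
    fr <- if (!is.null(getf) &&
              !methods::is(model, "oracleBlobClassifier")) getf(t) else NULL
    pr <- predictBlobs(model, blobs, frame = fr, frameIndex = t)
    lab <- colnames(pr)[max.col(pr, ties.method = "first")]
    sc <- pr[cbind(seq_len(nrow(pr)), max.col(pr, ties.method = "first"))]
    for (r in seq_len(nrow(sub))) {
      bl[[sub$trk[r]]]$blobLabel[sub$row[r]] <- lab[r]
      bl[[sub$trk[r]]]$blobScore[sub$row[r]] <- sc[r]
    }
  }
  graph@blobs <- bl
  graph
}

#' Aggregate per-blob labels into tracklet classifications
#'
#' The plurality ID among the tracklet's blob labels becomes the tracklet
#' label (ties are left unlabeled, conservatively). Tracklets whose
#' informative labels are predominantly "multi" are marked multi-animal.
#' The confidence score combines the mean classifier score of the blobs
#' agreeing with the plurality label, the fraction of agreeing blobs, and
#' a penalty for contradictory ID labels:
#' \deqn{conf = \bar{s}_{plur} (n_{plur} - n_{contra}) / n_{classified}}
#' clipped to [0, 1], where n_classified counts blobs not labeled
#' "unknown".
#'
#' @param graph a \linkS4class{TrackletGraph} whose blobs carry labels
#'   (see [classifyGraphBlobs()] or the `classifier` argument of
#'   [buildTrackletGraph()]).
#' @param minLabeledBlobs minimum number of plurality-ID blobs required to
#'   label a tracklet.
#' @return the graph with `kind`, `label` and `confidence` filled in its
#'   node table.
#' @export
classifyTracklets <- function(graph, minLabeledBlobs = 1) {
  nd <- graph@nodes
  for (i in seq_len(nTracklets(graph))) {
    b <- graph@blobs[[i]]
    if (is.null(b$blobLabel) || !nrow(b)) next
    labs <- b$blobLabel; scs <- b$blobScore
    isMulti <- labs == "multi"; isUnk <- labs == "unknown"
    isID <- !isMulti & !isUnk
    nID <- sum(isID); nMulti <- sum(isMulti)
    if (nID > nMulti) {
      tab <- sort(table(labs[isID]), decreasing = TRUE)
      plural <- names(tab)[1L]
      tie <- length(tab) > 1L && tab[2L] == tab[1L]
      nPlural <- tab[[1L]]
      nContra <- nID - nPlural
      nClassified <- nID + nMulti
      conf <- mean(scs[labs == plural]) * (nPlural - nContra) / nClassified
      conf <- min(max(conf, 0), 1)
      nd$kind[i] <- "single"
      if (!tie && nPlural >= minLabeledBlobs) {
        nd$label[i] <- plural
        nd$confidence[i] <- conf
      }
    } else if (nMulti > nID) {
      nd$kind[i] <- "multi"
    } else {
      # no informative majority (all "unknown", or an ID/multi tie):
      # leave the capacity open for the propagation solver
      nd$kind[i] <- "unknown"
    }
  }
  graph@nodes <- nd
  graph
}
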