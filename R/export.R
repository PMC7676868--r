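# Per-ID trajectory export and the validation measures: assignment rate,
# assignment error against ground truth, and exact Clopper-Pearson
# binomial confidence intervals.

#' Export per-ID trajectories from a solved graph
#'
#' One row per (ID, frame). Locations come from the blob centroid of the
#' tracklet the ID is assigned to. Flags: `single_classified` (the
#' tracklet was labeled with this ID directly by the classifier),
#' `single_propagated` (single-animal tracklet assigned by propagation),
#' `multi_propagated` (the ID sits in a multi-animal blob; the location is
#' the blob centroid and necessarily approximate), `unassigned` (no
#' assignment; no position is fabricated). Orientation is reported only
#' for single-animal rows: the blob's principal axis, with head/tail
#' resolved from the displacement direction where the animal moves at
#' least `speedMin` px/frame (averaged over +-`window` frames); below
#' that, the orientation is reported mod pi.
#'
#' @param solution an \linkS4class{IDSolution} from [solveGraph()].
#' @param graph the matching \linkS4class{TrackletGraph}.
#' @param speedMin displacement threshold (px/frame) for head/tail
#'   disambiguation.
#' @param window half-window (frames) for the displacement average.
#' @return data.frame `id`, `frame`, `x`, `y`, `orientation`, `flag`,
#'   `tracklet` (NA when unassigned).
#' @export
exportTrajectories <- function(solution, graph, speedMin = 1, window = 5) {
  ids <- idLabels(solution)
  nd <- trackletNodes(graph)
  Tn <- nFrames(graph)
  out <- expand.grid(frame = seq_len(Tn), id = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("id", "frame")]
  out$x <- NA_real_; out$y <- NA_real_; out$orientation <- NA_real_
  out$flag <- "unassigned"; out$tracklet <- NA_integer_
  S <- assignedIDs(solution)
  for (k in seq_along(ids)) {
    for (v in which(S[, k])) {
      b <- trackletBlobs(graph)[[v]]
      rows <- (k - 1L) * Tn + b$frame
      out$x[rows] <- b$x; out$y[rows] <- b$y
      out$tracklet[rows] <- v
      if (nd$kind[v] == "single") {
        direct <- !is.na(nd$label[v]) && nd$label[v] == ids[k] &&
          identical(solution@provenance[v, k], "classifier")
        out$flag[rows] <- if (direct) "single_classified"
                          else "single_propagated"
        out$orientation[rows] <- .resolveHeading(b, speedMin, window)
      } else {
        out$flag[rows] <- "multi_propagated"
      }
    }
  }
  rownames(out) <- NULL
  out
}

# head/tail disambiguation: pick the representative theta in {phi, phi+pi}
# closest to the local displacement direction when the animal moves
.resolveHeading <- function(b, speedMin, window) {
  n <- nrow(b)
  ori <- .wrapOrient(b$orient)
  res <- ori
  if (n < 2L) return(res)
  for (j in seq_len(n)) {
    lo <- max(1L, j - window); hi <- min(n, j + window)
    if (hi == lo) next
    dx <- b$x[hi] - b$x[lo]; dy <- b$y[hi] - b$y[lo]
    sp <- sqrt(dx^2 + dy^2) / (hi - lo)
    if (is.na(ori[j]) || sp < speedMin) next
    mv <- atan2(dy, dx)
    cand <- c(ori[j], ori[j] + pi)
    d <- abs(.wrapAngle(cand - mv))
    res[j] <- .wrapAngle(cand[which.min(d)])
  }
  res
}

#' Assignment rate
#'
#' Ratio of assigned locations to the total possible assignments (number
#' of IDs times number of frames).
#'
#' @param table trajectory table from [exportTrajectories()].
#' @param nIds,nFrames denominator terms; default inferred from the table.
#' @return a number in [0, 1].
#' @export
assignmentRate <- function(table, nIds = length(unique(table$id)),
                           nFrames = max(table$frame)) {
  if (nIds * nFrames == 0) stop("nIds x nFrames must be positive")
  sum(table$flag != "unassigned") / (nIds * nFrames)
}

#' Assignment error against ground truth
#'
#' Automated analogue of human spot-checking: an assignment is judged
#' correct if, for single-animal flags, the assigned location is within
#' `matchRadius` of the true position of that ID, and for multi-animal
#' flags, the true position falls inside the assigned blob's mask (dilated
#' by 1 px). Either the full census of assignments is judged, or a random
#' uniform subsample of `nPoints` of them (the protocol used for manual
#' validation of long recordings).
#'
#' @param table trajectory table from [exportTrajectories()].
#' @param gt ground-truth table (columns `frame`, `id`, `x`, `y`), e.g.
#'   from [groundTruth()].
#' @param graph the \linkS4class{TrackletGraph} (for blob masks; if NULL,
#'   multi rows are judged by distance <= 2 x matchRadius to the blob
#'   centroid).
#' @param matchRadius radius in px for single-animal rows (default one
#'   body length, 14).
#' @param nPoints NULL for a full census, or the number of sampled
#'   assignments to judge.
#' @param seed RNG seed for subsampling.
#' @param alpha 1 - confidence level of the Clopper-Pearson interval.
#' @return list: `nCorrect`, `nIncorrect`, `assignmentError`, `ci95`
#'   (lo, hi), `nJudged`.
#' @export
assignmentError <- function(table, gt, graph = NULL, matchRadius = 14,
                            nPoints = NULL, seed = 1, alpha = 0.05) {
  asg <- table[table$flag != "unassigned", , drop = FALSE]
  if (!nrow(asg)) stop("no assignments to judge")
  if (!is.null(nPoints)) {
    n <- min(nPoints, nrow(asg))
    pick <- .withSeed(seed, sample.int(nrow(asg), n))
    asg <- asg[pick, , drop = FALSE]
  }
  key <- paste(gt$frame, gt$id)
  hit <- match(paste(asg$frame, asg$id), key)
  if (anyNA(hit))
    stop("ground truth does not cover all judged frames/IDs")
  tx <- gt$x[hit]; ty <- gt$y[hit]
  correct <- logical(nrow(asg))
  isSingle <- asg$flag %in% c("single_classified", "single_propagated")
  d <- sqrt((asg$x - tx)^2 + (asg$y - ty)^2)
  correct[isSingle] <- d[isSingle] <= matchRadius
  im <- which(!isSingle)
  if (length(im)) {
    if (!is.null(graph)) {
      h <- graph@frameDim[1L]; w <- graph@frameDim[2L]
      for (r in im) {
        v <- asg$tracklet[r]
        b <- trackletBlobs(graph)[[v]]
        mask <- b$mask[[match(asg$frame[r], b$frame)]]
        gx <- as.integer(round(tx[r])); gy <- as.integer(round(ty[r]))
        ok <- FALSE
        for (ox in -1:1) { for (oy in -1:1) {
          px <- gx + ox; py <- gy + oy
          if (px >= 0L && px < w && py >= 0L && py < h &&
              .xyToPx(px, py, h) %in% mask) { ok <- TRUE; break }
        }; if (ok) break }
        correct[r] <- ok
      }
    } else {
      correct[im] <- d[im] <= 2 * matchRadius
    }
  }
  k <- sum(!correct); n <- length(correct)
  ci <- clopperPearson(k, n, alpha)
  list(nCorrect = sum(correct), nIncorrect = k,
       assignmentError = k / n, ci95 = ci, nJudged = n)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion via Beta quantiles:
#' lower = qbeta(alpha/2; k, n - k + 1), upper =
#' qbeta(1 - alpha/2; k + 1, n - k), with lower = 0 at k = 0 and
#' upper = 1 at k = n.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param alpha 1 - confidence level, in (0, 1).
#' @return numeric c(lo, hi).
#' @examples
#' clopperPearson(0, 500)   # c(0, 0.00736...)
#' @export
clopperPearson <- function(k, n, alpha = 0.05) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L ||
      length(n) != 1L || is.na(k) || is.na(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1")
  .assertScalarNum(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}
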