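# Frame-to-frame blob linking.
#
# A link (p, c) states that some or all animals of prev-frame blob p are in
# current-frame blob c. Exclusively overlapping pairs are linked directly
# (fast path); every other case goes through dense optical flow: the prev
# blob's pixels are advected by the flow field and a link is created to
# each current blob (dilated by 1 px) that captures at least `supportMin`
# of them. A blob that supports no candidate gets no link -- unlinked blobs
# are legitimate and open/close tracklets.

# label image (integer vector of length h*w) from a blob table
.labelImage <- function(blobs, frameDim) {
  lab <- integer(prod(frameDim))
  for (i in seq_len(nrow(blobs))) lab[blobs$mask[[i]]] <- i
  lab
}

# look up label at (x, y), falling back to the most common nonzero label
# in the 8-neighborhood (equivalent to dilating each blob by 1 px)
.labelAt <- function(lab, x, y, h, w) {
  out <- integer(length(x))
  ok <- x >= 0L & x < w & y >= 0L & y < h
  out[ok] <- lab[.xyToPx(x[ok], y[ok], h)]
  miss <- which(ok & out == 0L)
  if (length(miss)) {
    neigh <- expand.grid(ox = -1:1, oy = -1:1)
    neigh <- neigh[!(neigh$ox == 0 & neigh$oy == 0), ]
    votes <- matrix(0L, length(miss), nrow(neigh))
    for (k in seq_len(nrow(neigh))) {
      nx <- x[miss] + neigh$ox[k]; ny <- y[miss] + neigh$oy[k]
      okn <- nx >= 0L & nx < w & ny >= 0L & ny < h
      v <- integer(length(miss))
      v[okn] <- lab[.xyToPx(nx[okn], ny[okn], h)]
      votes[, k] <- v
    }
    out[miss] <- apply(votes, 1L, function(v) {
      v <- v[v > 0L]
      if (!length(v)) 0L else as.integer(names(which.max(table(v))))
    })
  }
  out
}

#' Link blobs across two consecutive frames
#'
#' @param blobsPrev,blobsCur blob tables from [segmentFrame()] for frames
#'   t - 1 and t.
#' @param framePrev,frameCur the corresponding frames (needed only when an
#'   ambiguous case requires optical flow).
#' @param frameDim c(height, width).
#' @param supportMin minimum link support: the fraction of an animal's
#'   worth of pixels (see `refArea`) that must flow from the previous blob
#'   into the current one.
#' @param searchPx flow search radius in pixels.
#' @param flowStride flow sampling stride (see [estimateFlow()]).
#' @param refArea reference single-animal area in px used to normalize
#'   support; defaults to the smaller blob of each candidate pair. In
#'   aggregates a leaving/joining animal contributes only a small share of
#'   either blob's pixels, so normalizing by one body keeps such links.
#' @return data.frame of links: `prev`, `cur` (row indices into the blob
#'   tables) and `support` in [0, 1].
#' @export
linkBlobs <- function(blobsPrev, blobsCur, framePrev = NULL, frameCur = NULL,
                      frameDim, supportMin = 0.25, searchPx = 8,
                      flowStride = 2L, refArea = NULL) {
  np <- nrow(blobsPrev); nc <- nrow(blobsCur)
  empty <- data.frame(prev = integer(0), cur = integer(0),
                      support = numeric(0))
  if (np == 0L || nc == 0L) return(empty)
  h <- frameDim[1L]; w <- frameDim[2L]

  curLab <- .labelImage(blobsCur, frameDim)
  # pixel-overlap counts prev x cur
  ov <- matrix(0L, np, nc)
  for (i in seq_len(np)) {
    tab <- tabulate(curLab[blobsPrev$mask[[i]]], nbins = nc)
    ov[i, ] <- tab
  }

  # candidate relation: overlap, or bbox proximity within the search radius
  cand <- ov > 0L
  margin <- searchPx + 2L
  for (i in seq_len(np)) {
    bb <- blobsPrev$bbox[[i]]
    for (j in seq_len(nc)) {
      if (cand[i, j]) next
      cb <- blobsCur$bbox[[j]]
      if (bb[1L] - margin < cb[3L] && cb[1L] - margin < bb[3L] &&
          bb[2L] - margin < cb[4L] && cb[2L] - margin < bb[4L])
        cand[i, j] <- TRUE
    }
  }

  # connected components of the bipartite candidate graph
  comp <- .bipartiteComponents(cand)
  links <- empty
  for (grp in comp) {
    ip <- grp$prev; ic <- grp$cur
    if (!length(ip) || !length(ic)) next
    if (length(ip) == 1L && length(ic) == 1L && ov[ip, ic] > 0L) {
      # exclusive overlap: fast path, no flow needed
      links <- rbind(links, data.frame(prev = ip, cur = ic, support = 1))
      next
    }
    if (is.null(framePrev) || is.null(frameCur))
      stop("ambiguous linking requires the frames for optical flow")
    bbs <- c(blobsPrev$bbox[ip], blobsCur$bbox[ic])
    region <- c(min(vapply(bbs, `[`, numeric(1), 1L)) - margin,
                min(vapply(bbs, `[`, numeric(1), 2L)) - margin,
                max(vapply(bbs, `[`, numeric(1), 3L)) + margin,
                max(vapply(bbs, `[`, numeric(1), 4L)) + margin)
    fl <- estimateFlow(framePrev, frameCur, region, searchPx = searchPx,
                       stride = flowStride)
    rx0 <- fl$bbox[1L]; ry0 <- fl$bbox[2L]
    for (i in ip) {
      xy <- .pxToXY(blobsPrev$mask[[i]], h)
      rrow <- xy[, "y"] - ry0 + 1L; rcol <- xy[, "x"] - rx0 + 1L
      inR <- rrow >= 1L & rrow <= nrow(fl$dx) & rcol >= 1L & rcol <= ncol(fl$dx)
      lx <- xy[, "x"]; ly <- xy[, "y"]
      sub <- cbind(rrow[inR], rcol[inR])
      lx[inR] <- lx[inR] + fl$dx[sub]
      ly[inR] <- ly[inR] + fl$dy[sub]
      lnd <- .labelAt(curLab, as.integer(round(lx)), as.integer(round(ly)), h, w)
      cnt <- tabulate(lnd, nbins = nc)
      # evidence of animal flow = advected landings or direct mask overlap
      # (flow can misjudge occluded, stationary animals, and a missed link
      # severs an animal's path through the graph, which is far worse for
      # the downstream inference than a spurious one), normalized by one
      # animal's area
      denom <- pmin(length(lx), blobsCur$area)
      if (!is.null(refArea)) denom <- pmin(denom, refArea)
      supp <- pmin(pmax(cnt, ov[i, ]) / denom, 1)
      for (j in ic) {
        if (supp[j] >= supportMin)
          links <- rbind(links,
                         data.frame(prev = i, cur = j, support = supp[j]))
      }
    }
  }
  links[order(links$prev, links$cur), , drop = FALSE]
}

.bipartiteComponents <- function(cand) {
  np <- nrow(cand); nc <- ncol(cand)
  n <- np + nc
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- which(cand, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ri <- find(idx[r, 1L]); rj <- find(np + idx[r, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(rt) {
    members <- which(roots == rt)
    list(prev = members[members <= np],
         cur = members[members > np] - np)
  })
}
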