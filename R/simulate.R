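# Synthetic arena: correlated random walk with heading persistence,
# soft-core repulsion at short range, and optional attraction to neighbors
# that produces transient aggregates -- the tracker's hard cases
# (merged blobs, occluded tags).

# distance between two segments P0-P1 and Q0-Q1 (each a length-2 vector pair)
.segDist <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c1 <- sum(d1 * r)
    if (e <= 1e-12) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-12) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  cp <- p0 + s * d1; cq <- q0 + t * d2
  sqrt(sum((cp - cq)^2))
}

# body axis segment endpoints for all agents (matrix n x 4: x0 y0 x1 y1)
.bodySegments <- function(x, y, heading, bodyLength, bodyWidth) {
  h <- pmax(bodyLength / 2 - bodyWidth / 2, 0.5)
  cbind(x - h * cos(heading), y - h * sin(heading),
        x + h * cos(heading), y + h * sin(heading))
}

# touch graph: capsule (body) distance below contact gap; returns cluster
# index per agent via union-find
.contactClusters <- function(x, y, heading, bodyLength, bodyWidth,
                             gap = 1.5) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  seg <- .bodySegments(x, y, heading, bodyLength, bodyWidth)
  maxReach <- bodyLength + gap
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq.int(i + 1L, n)) {
    if (abs(x[i] - x[j]) > maxReach[i] || abs(y[i] - y[j]) > maxReach[i]) next
    thr <- (bodyWidth[i] + bodyWidth[j]) / 2 + gap
    d <- .segDist(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])
    if (d <= thr) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Simulate color-tagged agents in a bounded 2D arena
#'
#' Agents follow a correlated random walk (heading persistence with
#' Gaussian turning noise), alternate between moving and resting, repel
#' softly at very short range (so bodies may touch and overlap but not
#' coincide), and, when \code{attraction > 0}, steer toward nearby
#' neighbors and rest longer in contact -- which makes transient
#' aggregates form and dissolve. All randomness comes from \code{seed};
#' repeated calls with identical inputs give identical ground truth.
#'
#' @param agents roster from [colonyAgents()] or rbind-ed [agentSpec()] rows.
#' @param arena from [arenaSpec()].
#' @param nFrames number of frames to simulate (>= 1).
#' @param motion named list overriding motion defaults: \code{turnSd}
#'   (rad/frame), \code{attraction} (0-1), \code{attractRadius} (px),
#'   \code{restProb}, \code{wakeProb} (per-frame switch probabilities),
#'   \code{contactRest} (extra rest bias in contact, scaled by attraction).
#' @param seed integer RNG seed.
#' @return an \linkS4class{ArenaSimulation}.
#' @examples
#' sim <- simulateColony(colonyAgents(2), arenaSpec(96, 96), nFrames = 20,
#'                       seed = 1)
#' head(groundTruth(sim))
#' @export
simulateColony <- function(agents, arena, nFrames,
                           motion = list(), seed = 1) {
  if (!is.data.frame(agents) || nrow(agents) < 1L)
    stop("'agents' must be a non-empty agent roster")
  if (anyDuplicated(agents$id)) stop("agent id labels must be unique")
  if (!is.list(arena) || is.null(arena$width))
    stop("'arena' must come from arenaSpec()")
  .assertScalarNum(nFrames, "nFrames", lower = 1)
  nFrames <- as.integer(nFrames)

  mp <- list(turnSd = 0.35, attraction = 0.5, attractRadius = 45,
             restProb = 0.03, wakeProb = 0.06, contactRest = 0.25)
  mp[names(motion)] <- motion
  .assertScalarNum(mp$attraction, "attraction", lower = 0, upper = 1)

  n <- nrow(agents)
  L <- agents$bodyLength; W <- agents$bodyWidth; spd <- agents$speed
  margin <- max(L) / 2 + 1
  if (arena$width - 2 * margin < 4 || arena$height - 2 * margin < 4)
    stop("arena too small for the agents' body length")

  out <- .withSeed(seed, {
    # non-overlapping initial placement
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:500) {
        xi <- runif(1, margin, arena$width - 1 - margin)
        yi <- runif(1, margin, arena$height - 1 - margin)
        if (i == 1L || all((x[seq_len(i - 1L)] - xi)^2 +
                           (y[seq_len(i - 1L)] - yi)^2 > (1.3 * max(L))^2)) break
      }
      x[i] <- xi; y[i] <- yi
    }
    heading <- runif(n, -pi, pi)
    resting <- rep(FALSE, n)

    N <- nFrames * n
    G <- list(frame = integer(N), id = character(N), x = numeric(N),
              y = numeric(N), heading = numeric(N), present = logical(N),
              aggregate = integer(N), drawOrder = integer(N))
    for (t in seq_len(nFrames)) {
      if (t > 1L) {
        dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
        d2 <- dx^2 + dy^2; diag(d2) <- Inf
        near <- d2 < mp$attractRadius^2
        inContact <- apply(d2 < (1.2 * max(L))^2, 1L, any)

        # mode switching: contact + attraction favors resting (aggregates
        # persist); lone agents wake sooner
        pRest <- mp$restProb + mp$attraction * mp$contactRest * inContact
        pWake <- mp$wakeProb * ifelse(inContact, 1 - 0.85 * mp$attraction, 1.5)
        u <- runif(n)
        resting <- ifelse(resting, u > pWake, u < pRest)

        # heading: persistence + noise + steering toward nearest neighbor
        turn <- rnorm(n, 0, mp$turnSd)
        if (mp$attraction > 0) {
          for (i in which(!resting & apply(near, 1L, any))) {
            j <- which.min(d2[i, ])
            bear <- atan2(y[j] - y[i], x[j] - x[i])
            turn[i] <- turn[i] + 0.35 * mp$attraction * .wrapAngle(bear - heading[i])
          }
        }
        heading <- .wrapAngle(heading + ifelse(resting, 0, turn))

        step <- ifelse(resting, 0, spd * runif(n, 0.6, 1))
        x <- x + step * cos(heading)
        y <- y + step * sin(heading)

        # soft-core repulsion: capped nudge keeps bodies from coinciding
        # while still allowing touching/overlap (merged blobs)
        dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
        d2 <- dx^2 + dy^2; diag(d2) <- Inf
        sep <- 0.45 * outer(L, L, function(a, b) (a + b) / 2)
        tooClose <- which(d2 < sep^2 & upper.tri(d2), arr.ind = TRUE)
        if (nrow(tooClose)) for (r in seq_len(nrow(tooClose))) {
          i <- tooClose[r, 1L]; j <- tooClose[r, 2L]
          d <- sqrt(d2[i, j]); if (d < 1e-6) { d <- 1e-6 }
          push <- min((sep[i, j] - d) / 2, 1)
          ux <- (x[i] - x[j]) / d; uy <- (y[i] - y[j]) / d
          x[i] <- x[i] + push * ux; y[i] <- y[i] + push * uy
          x[j] <- x[j] - push * ux; y[j] <- y[j] - push * uy
        }

        # boundary: reflect at a body-length margin when closed; free when open
        if (!arena$openBoundary) {
          lo <- margin
          hix <- arena$width - 1 - margin; hiy <- arena$height - 1 - margin
          bounced <- x < lo | x > hix | y < lo | y > hiy
          x <- pmin(pmax(x, lo), hix); y <- pmin(pmax(y, lo), hiy)
          heading[bounced] <- .wrapAngle(heading[bounced] + pi)
        }
      }

      agg <- .contactClusters(x, y, heading, L, W)
      present <- if (arena$openBoundary) {
        xi <- pmin(pmax(round(x), 0), arena$width - 1)
        yi <- pmin(pmax(round(y), 0), arena$height - 1)
        inFrame <- x >= 0 & x <= arena$width - 1 & y >= 0 & y <= arena$height - 1
        inFrame & arena$roiMask[cbind(yi + 1, xi + 1)]
      } else rep(TRUE, n)

      idx <- ((t - 1L) * n + 1L):(t * n)
      G$frame[idx] <- t; G$id[idx] <- agents$id
      G$x[idx] <- x; G$y[idx] <- y; G$heading[idx] <- heading
      G$present[idx] <- present; G$aggregate[idx] <- agg
      G$drawOrder[idx] <- sample.int(n)
    }
    as.data.frame(G, stringsAsFactors = FALSE)
  })

  methods::new("ArenaSimulation", agents = agents, arena = arena, gt = out,
               nFrames = nFrames, motion = mp, seed = as.integer(seed))
}

#' Preset small-colony simulation
#'
#' A canonical test condition: 16 agents marked with ordered pairs of four
#' tag colors, a closed 256 x 256 px arena, aggregation switched on.
#'
#' @param nFrames number of frames (default 2000).
#' @param seed RNG seed.
#' @return an \linkS4class{ArenaSimulation}.
#' @export
smallColonySim <- function(nFrames = 2000, seed = 16) {
  simulateColony(colonyAgents(16, colors = c("B", "G", "O", "P"), nTags = 2),
                 arenaSpec(256, 256), nFrames = nFrames,
                 motion = list(attraction = 0.6), seed = seed)
}

#' Build a simulation from scripted trajectories
#'
#' Wraps a choreographed position table as an \linkS4class{ArenaSimulation}
#' (aggregate labels computed with the same body-contact rule as
#' [simulateColony()]). Useful for deterministic fixtures such as staged
#' merge/split events.
#'
#' @param agents agent roster.
#' @param arena from [arenaSpec()].
#' @param track data.frame with columns `frame`, `id`, `x`, `y`,
#'   `heading`; every (frame, id) pair present in the arena must appear.
#' @param seed seed stored for rendering noise.
#' @return an \linkS4class{ArenaSimulation}.
#' @export
scriptedColony <- function(agents, arena, track, seed = 1) {
  need <- c("frame", "id", "x", "y", "heading")
  if (!all(need %in% names(track))) stop("track must have columns frame, id, x, y, heading")
  track <- track[order(track$frame, match(track$id, agents$id)), , drop = FALSE]
  nF <- max(track$frame)
  gt <- do.call(rbind, lapply(seq_len(nF), function(t) {
    g <- track[track$frame == t, , drop = FALSE]
    rows <- match(g$id, agents$id)
    agg <- .contactClusters(g$x, g$y, g$heading, agents$bodyLength[rows],
                            agents$bodyWidth[rows])
    data.frame(frame = t, id = g$id, x = g$x, y = g$y, heading = g$heading,
               present = TRUE, aggregate = agg,
               drawOrder = seq_len(nrow(g)), stringsAsFactors = FALSE)
  }))
  methods::new("ArenaSimulation", agents = agents, arena = arena, gt = gt,
               nFrames = as.integer(nF), motion = list(scripted = TRUE),
               seed = as.integer(seed))
}
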