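#' Tag color palette
#'
#' Saturated paint colors commonly used to mark insects: blue (B), green
#' (G), orange (O), pink (P), yellow (Y), cyan (C), white (W). Values are
#' RGB triples in [0, 1].
#'
#' @param which character vector of color initials; default all seven.
#' @return named list of RGB triples.
#' @export
tagPalette <- function(which = c("B", "G", "O", "P", "Y", "C", "W")) {
  pal <- list(B = c(0.10, 0.20, 0.95), G = c(0.10, 0.85, 0.20),
              O = c(1.00, 0.55, 0.05), P = c(1.00, 0.35, 0.75),
              Y = c(0.95, 0.90, 0.10), C = c(0.10, 0.85, 0.90),
              W = c(0.98, 0.98, 0.98))
  miss <- setdiff(which, names(pal))
  if (length(miss)) stop("unknown tag colors: ", paste(miss, collapse = ", "))
  pal[which]
}

#' Specify one tagged agent
#'
#' @param id ID label, conventionally the tag color initials in order from
#'   head to gaster (e.g. "BG" = blue thorax tag, green abdomen tag).
#' @param tagColors list of 1-3 RGB triples, ordered head to tail.
#' @param bodyLength body length in pixels.
#' @param speed maximum displacement per frame in pixels.
#' @return one-row data.frame usable as a row of an agent roster.
#' @export
agentSpec <- function(id, tagColors, bodyLength = 14, speed = 2.5) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.list(tagColors) || length(tagColors) < 1L || length(tagColors) > 3L)
    stop("an agent carries 1 to 3 tags")
  .assertScalarNum(bodyLength, "bodyLength", lower = 4)
  .assertScalarNum(speed, "speed", lower = 0)
  data.frame(id = id, nTags = length(tagColors),
             tagColors = I(list(tagColors)),
             bodyLength = bodyLength, bodyWidth = round(bodyLength * 0.36),
             speed = speed, stringsAsFactors = FALSE)
}

#' Build a colony roster of distinctly tagged agents
#'
#' Enumerates ordered tag-color combinations (repeats allowed, as in real
#' colonies where e.g. "GG" is a valid double-green ant) and takes the
#' first \code{n}.
#'
#' @param n number of agents.
#' @param colors character vector of palette initials to draw from.
#' @param nTags tags per agent (1-3).
#' @inheritParams agentSpec
#' @return data.frame roster with \code{n} rows.
#' @examples
#' colonyAgents(16, colors = c("B", "G", "O", "P"), nTags = 2)$id
#' @export
colonyAgents <- function(n, colors = c("B", "G", "O", "P"), nTags = 2,
                         bodyLength = 14, speed = 2.5) {
  if (n < 1L) stop("'n' must be >= 1")
  if (nTags < 1L || nTags > 3L) stop("'nTags' must be 1, 2 or 3")
  combos <- do.call(expand.grid,
                    c(rep(list(colors), nTags),
                      list(stringsAsFactors = FALSE)))
  # vary the leading tag fastest so small n still spans many colors
  labels <- apply(combos, 1L, paste, collapse = "")
  if (n > length(labels))
    stop(sprintf("%d agents requested but only %d distinct %d-tag combinations exist",
                 n, length(labels), nTags))
  pal <- tagPalette(colors)
  do.call(rbind, lapply(labels[seq_len(n)], function(lab) {
    cols <- lapply(strsplit(lab, "")[[1L]], function(k) pal[[k]])
    agentSpec(lab, cols, bodyLength = bodyLength, speed = speed)
  }))
}

#' Specify the arena
#'
#' @param width,height frame dimensions in pixels.
#' @param roiMask logical height x width matrix of the tracked region;
#'   default the full frame.
#' @param openBoundary may agents leave/enter the ROI?
#' @return list with validated fields.
#' @export
arenaSpec <- function(width, height, roiMask = NULL, openBoundary = FALSE) {
  .assertScalarNum(width, "width", lower = 16)
  .assertScalarNum(height, "height", lower = 16)
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(roiMask)) roiMask <- matrix(TRUE, height, width)
  if (!is.logical(roiMask) || !all(dim(roiMask) == c(height, width)))
    stop("roiMask must be a logical height x width matrix")
  list(width = width, height = height, roiMask = roiMask,
       openBoundary = isTRUE(openBoundary))
}
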