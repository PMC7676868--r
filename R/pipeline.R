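# End-to-end orchestration: configuration validation, logging, and the
# simulate -> segment -> graph -> classify -> solve -> export chain.

#' Validated run configuration
#'
#' Central parameter set for the tracking pipeline, with documented
#' ranges. Every parameter is validated before any processing starts.
#'
#' @param ... overrides of the defaults: `threshold` (max-channel
#'   background difference, > 0), `minArea` (px, >= 1), `cropPx` (crop
#'   side, 0 disables), `supportMin` (advected-pixel link support,
#'   (0, 1]), `searchPx` (flow search radius, >= 1; about twice the largest expected per-frame displacement), `flowStride` (flow sampling stride), `bgSamples`
#'   (background median sample count, >= 3), `boundaryBand` (px),
#'   `openBoundary` (logical), `minLabeledBlobs` (>= 1), `matchRadius`
#'   (px, validation), `noiseSd` (render noise, >= 0), `seed` (integer).
#' @return a named list of class "runConfig".
#' @export
runConfig <- function(...) {
  cfg <- list(threshold = 0.3, minArea = 16, cropPx = 0, supportMin = 0.25,
              searchPx = 6, flowStride = 2, bgSamples = 9, boundaryBand = 6,
              openBoundary = FALSE, minLabeledBlobs = 1, matchRadius = 14,
              noiseSd = 0.02, seed = 1)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .assertScalarNum(cfg$threshold, "threshold", lower = 1e-9)
  .assertScalarNum(cfg$minArea, "minArea", lower = 1)
  .assertScalarNum(cfg$cropPx, "cropPx", lower = 0)
  .assertScalarNum(cfg$supportMin, "supportMin", lower = 1e-9, upper = 1)
  .assertScalarNum(cfg$searchPx, "searchPx", lower = 1)
  .assertScalarNum(cfg$flowStride, "flowStride", lower = 1)
  .assertScalarNum(cfg$bgSamples, "bgSamples", lower = 3)
  .assertScalarNum(cfg$boundaryBand, "boundaryBand", lower = 0)
  .assertScalarNum(cfg$minLabeledBlobs, "minLabeledBlobs", lower = 1)
  .assertScalarNum(cfg$matchRadius, "matchRadius", lower = 1e-9)
  .assertScalarNum(cfg$noiseSd, "noiseSd", lower = 0)
  .assertScalarNum(cfg$seed, "seed")
  if (!is.logical(cfg$openBoundary)) stop("openBoundary must be logical")
  structure(cfg, class = "runConfig")
}

#' Run the full tracking pipeline
#'
#' Orchestrates segmentation, tracklet-graph construction, classification,
#' ID propagation and trajectory export, writing all artifacts under
#' `outDir`: `graph/` (nodes, edges, blobs CSVs), `solution/`
#' (assignments, contradictions), `trajectories.csv` and `summary.json`
#' (stage counts, assignment rate, error vs ground truth when available,
#' config echo). Fully deterministic given the seeds in `config`.
#'
#' @param input an \linkS4class{ArenaSimulation}, a fixture directory
#'   written by [writeFixture()], or a [frameSource()] function.
#' @param outDir output directory (created).
#' @param config a [runConfig()].
#' @param classifier "oracle" (requires a simulation input), a trained
#'   blob classifier, or NULL to skip classification (graph only).
#' @param ids ID labels; default from the simulation roster or classifier.
#' @param verbose log stage counts to stderr.
#' @return invisibly, a list with the graph, solution, trajectory table
#'   and summary.
#' @export
runPipeline <- function(input, outDir, config = runConfig(),
                        classifier = "oracle", ids = NULL, verbose = TRUE) {
  if (!inherits(config, "runConfig")) config <- runConfig(config)
  sim <- NULL
  if (methods::is(input, "ArenaSimulation")) {
    sim <- input
    frames <- frameSource(sim, noiseSd = config$noiseSd, seed = config$seed)
  } else if (is.character(input)) {
    frames <- frameSourceFromDir(input)
  } else if (is.function(input)) {
    frames <- input
  } else stop("unsupported input")
  say <- function(...) if (verbose) message(sprintf(...))

  model <- NULL
  if (identical(classifier, "oracle")) {
    if (is.null(sim)) stop("the oracle classifier requires a simulation input")
    model <- oracleClassifier(sim)
  } else if (inherits(classifier, "blobClassifier")) {
    model <- classifier
  } else if (!is.null(classifier)) stop("unsupported classifier")
  if (is.null(ids)) {
    ids <- if (!is.null(sim)) sim@agents$id
           else if (!is.null(model)) setdiff(classifierClasses(model),
                                             c("multi", "unknown"))
  }

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say("building tracklet graph over %d frames", attr(frames, "nFrames"))
  graph <- buildTrackletGraph(frames, threshold = config$threshold,
                              minArea = config$minArea,
                              openBoundary = config$openBoundary,
                              boundaryBand = config$boundaryBand,
                              supportMin = config$supportMin,
                              searchPx = config$searchPx,
                              flowStride = config$flowStride,
                              bgSamples = config$bgSamples,
                              cropPx = config$cropPx,
                              classifier = model, verbose = verbose)
  say("graph: %d tracklets, %d edges", nTracklets(graph),
      nrow(trackletEdges(graph)))
  writeGraph(graph, file.path(outDir, "graph"))

  solution <- NULL; traj <- NULL
  summary <- list(nTracklets = nTracklets(graph),
                  nEdges = nrow(trackletEdges(graph)),
                  config = unclass(config))
  if (!is.null(model) && length(ids)) {
    graph <- classifyTracklets(graph, minLabeledBlobs = config$minLabeledBlobs)
    seeds <- rankSeeds(graph)
    say("classification: %d seeds over %d IDs", nrow(seeds), length(ids))
    solution <- solveGraph(graph, ids = ids, seeds = seeds)
    writeSolution(solution, file.path(outDir, "solution"))
    traj <- exportTrajectories(solution, graph)
    write.csv(traj, file.path(outDir, "trajectories.csv"), row.names = FALSE)
    summary$nSeeds <- nrow(seeds)
    summary$nAssignments <- sum(assignedIDs(solution))
    summary$nContradicted <- nrow(solution@contradicted)
    summary$assignmentRate <- assignmentRate(traj, length(ids),
                                             nFrames(graph))
    say("solution: %d assignments, rate %.3f", summary$nAssignments,
        summary$assignmentRate)
    if (!is.null(sim)) {
      err <- assignmentError(traj, groundTruth(sim), graph,
                             matchRadius = config$matchRadius)
      summary$assignmentError <- err$assignmentError
      summary$errorCI95 <- err$ci95
      say("census error vs ground truth: %.4f", err$assignmentError)
    }
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(graph = graph, solution = solution, trajectories = traj,
                 summary = summary))
}
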