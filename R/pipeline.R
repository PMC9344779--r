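# Desk-scale orchestration: corpus generation -> window dataset ->
# configuration grid -> detector training -> matched-region comparison.
# Every stage derives its seed deterministically from the global seed, so
# non-training stages are bit-reproducible end to end.

#' Create a run configuration
#'
#' Defaults mirror the study conditions: 1024 x 1280 fields, 394 windows
#' per class (788 total) split 3:1, the 9-row configuration grid, and a
#' 10-image evaluation set kept disjoint from training by construction
#' (separate seed stream).
#'
#' @param scene [SceneConfig-class] template; its seed is overridden per
#'   generated scene.
#' @param nTrainScenes scenes generated for dataset assembly and detector
#'   training.
#' @param nEvalScenes held-out evaluation scenes.
#' @param nPerClass balanced windows per label.
#' @param trainFraction train split fraction.
#' @param grid list of [PatchClassifierConfig-class].
#' @param overfitGap overlearning flag threshold.
#' @param redThreshold,yellowThreshold overlay bands.
#' @param detector list of instance-backend options (`backend`
#'   `"segmenter"` or `"oracle"`, `epochs`, `scoreThreshold`,
#'   `nmsThreshold`, `minArea`).
#' @param globalSeed master seed.
#' @param outputDir artifact directory.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(scene = sceneConfig(), nTrainScenes = 20L,
                      nEvalScenes = 10L, nPerClass = 394L,
                      trainFraction = 0.75, grid = defaultConfigGrid(),
                      overfitGap = 0.05, redThreshold = 0.9,
                      yellowThreshold = 0.5,
                      detector = list(backend = "segmenter", epochs = 10L,
                                      scoreThreshold = 0.5, nmsThreshold = 0.5,
                                      minArea = 20L),
                      globalSeed = 1L, outputDir = "cytodetect-run") {
  new("RunConfig", scene = scene, nTrainScenes = as.integer(nTrainScenes),
      nEvalScenes = as.integer(nEvalScenes), nPerClass = as.integer(nPerClass),
      trainFraction = as.numeric(trainFraction), grid = grid,
      overfitGap = as.numeric(overfitGap),
      redThreshold = as.numeric(redThreshold),
      yellowThreshold = as.numeric(yellowThreshold),
      detector = detector, globalSeed = as.integer(globalSeed),
      outputDir = outputDir)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(paste0("RunConfig: %d train + %d eval scenes, %d windows/class, ",
                     "split %.2f, %d grid configs, seed %d -> '%s'\n"),
              object@nTrainScenes, object@nEvalScenes, object@nPerClass,
              object@trainFraction, length(object@grid), object@globalSeed,
              object@outputDir))
})

# ---- YAML round-trip -------------------------------------------------------

sceneConfigAsList <- function(s) {
  list(nBlue = s@nBlue, nRed = s@nRed, imageSize = s@imageSize,
       nucleusRadiusRange = s@nucleusRadiusRange, ncRatioRange = s@ncRatioRange,
       debrisDensity = s@debrisDensity, overlapFraction = s@overlapFraction,
       stainNoiseSd = s@stainNoiseSd, seed = s@seed)
}

classifierConfigAsList <- function(c) {
  list(activation = c@activation, epochs = c@epochs, nLayers = c@nLayers,
       dropoutRate = c@dropoutRate, learningSeed = c@learningSeed,
       batchSize = c@batchSize, learningRate = c@learningRate)
}

#' Serialize / restore a run configuration
#'
#' `saveRunConfig()` writes YAML; `loadRunConfig()` reads it back so that
#' `loadRunConfig(saveRunConfig(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @return `saveRunConfig`: (invisibly) `path`; `loadRunConfig`: a
#'   [RunConfig-class].
#' @export
saveRunConfig <- function(config, path) {
  obj <- list(
    scene = sceneConfigAsList(config@scene),
    nTrainScenes = config@nTrainScenes, nEvalScenes = config@nEvalScenes,
    nPerClass = config@nPerClass, trainFraction = config@trainFraction,
    grid = lapply(config@grid, classifierConfigAsList),
    overfitGap = config@overfitGap, redThreshold = config@redThreshold,
    yellowThreshold = config@yellowThreshold, detector = config@detector,
    globalSeed = config@globalSeed, outputDir = config@outputDir)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  o <- yaml::read_yaml(path)
  runConfig(
    scene = do.call(sceneConfig, o$scene),
    nTrainScenes = o$nTrainScenes, nEvalScenes = o$nEvalScenes,
    nPerClass = o$nPerClass, trainFraction = o$trainFraction,
    grid = lapply(o$grid, function(g) do.call(patchClassifierConfig, g)),
    overfitGap = o$overfitGap, redThreshold = o$redThreshold,
    yellowThreshold = o$yellowThreshold, detector = o$detector,
    globalSeed = o$globalSeed, outputDir = o$outputDir)
}

# Scene configs for the train / eval corpora (separate seed streams, so
# the two sets are disjoint by construction).
corpusConfigs <- function(config, which = c("train", "eval")) {
  which <- match.arg(which)
  n <- if (which == "train") config@nTrainScenes else config@nEvalScenes
  base <- deriveSeed(config@globalSeed, if (which == "train") "scenes" else "eval")
  lapply(seq_len(n), function(i) {
    s <- config@scene
    s@seed <- as.integer((base + i * 131L) %% 2147483647L)
    s
  })
}

provenance <- function(config, extra = list()) {
  c(list(package = "cytodetect",
         version = as.character(utils::packageVersion("cytodetect")),
         globalSeed = config@globalSeed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Run the sliding-window experiment end to end
#'
#' Generates the training corpus, assembles and splits the balanced window
#' dataset (index CSV), trains every grid configuration (grid report CSV),
#' then scores the held-out evaluation scenes with the best
#' non-overlearned classifier: probability overlays (PNG) and pooled
#' window-mode matched-region metrics (JSON + CSV). Stages log one message
#' each; artifacts written before a failure are retained.
#'
#' @param config a [RunConfig-class].
#' @param writePatches also export individual window PNGs.
#' @return list with `dataset`, `grid`, `best`, `evalScenes` (configs),
#'   `metrics`, `matches` and `paths`.
#' @export
runSwmExperiment <- function(config, writePatches = FALSE) {
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  message("stage 1/5 [corpus]: generating ", config@nTrainScenes, " training scene(s)")
  trainCfgs <- corpusConfigs(config, "train")

  message("stage 2/5 [windows]: assembling ", 2L * config@nPerClass,
          " balanced windows and splitting")
  samples <- assembleBalancedDataset(trainCfgs, config@nPerClass,
                                     seed = deriveSeed(config@globalSeed, "windows"))
  dataset <- splitDataset(samples, config@trainFraction,
                          seed = deriveSeed(config@globalSeed, "split"))
  paths$datasetIndex <- exportWindowDataset(dataset, file.path(config@outputDir, "windows"),
                                            writePatches = writePatches)

  message("stage 3/5 [grid]: training ", length(config@grid), " configuration(s)")
  grid <- runConfigGrid(dataset, config@grid, overfitGap = config@overfitGap)
  paths$gridReport <- file.path(config@outputDir, "grid_report.csv")
  utils::write.csv(grid$report, paths$gridReport, row.names = FALSE)
  best <- bestGridResult(grid)

  message("stage 4/5 [overlays]: scoring ", config@nEvalScenes, " evaluation scene(s)")
  evalCfgs <- corpusConfigs(config, "eval")
  overlayDir <- file.path(config@outputDir, "overlays")
  dir.create(overlayDir, showWarnings = FALSE)
  matches <- vector("list", length(evalCfgs))
  for (i in seq_along(evalCfgs)) {
    scene <- generateScene(evalCfgs[[i]])
    pmap <- scoreImage(best, scene@image, sourceId = scene@id)
    ov <- renderOverlay(scene@image, pmap, config@redThreshold, config@yellowThreshold)
    p <- file.path(overlayDir, paste0(scene@id, "_overlay.png"))
    png::writePNG(ov, p)
    paths$overlays <- c(paths$overlays, p)
    matches[[i]] <- matchDetections(windowDetections(pmap, config@yellowThreshold),
                                    scene, mode = "window")
  }

  message("stage 5/5 [metrics]: pooled window-mode matched-region metrics")
  pooled <- combineMatchResults(matches)
  metrics <- computeMetrics(pooled)
  paths$metrics <- file.path(config@outputDir, "swm_metrics.json")
  jsonlite::write_json(as.list(metricsAsRow(metrics)), paths$metrics,
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(metricsAsRow(metrics),
                   file.path(config@outputDir, "swm_metrics.csv"),
                   row.names = FALSE)
  paths$provenance <- file.path(config@outputDir, "provenance.json")
  jsonlite::write_json(provenance(config, list(stage = "swm")),
                       paths$provenance, auto_unbox = TRUE)

  list(dataset = dataset, grid = grid, best = best, evalScenes = evalCfgs,
       matches = matches, metrics = metrics, paths = paths)
}

#' Compare the sliding-window and instance backends
#'
#' Runs both detectors over the same held-out evaluation scenes and emits
#' the four-criterion comparison table. The sliding-window side reuses a
#' supplied [TrainResult-class] (or trains the best grid configuration via
#' [runSwmExperiment()] machinery); the instance side is either the
#' trainable pixel segmenter (fitted on the training corpus) or the
#' hue-threshold reference detector.
#'
#' @param config a [RunConfig-class].
#' @param swmResult optional pre-trained [TrainResult-class].
#' @param dataset optional pre-built [WindowDataset-class] (required when
#'   `swmResult` is missing).
#' @return list with `table` (comparison data.frame), `swmMatch`,
#'   `instanceMatch`, `segmenter` and `paths`.
#' @export
runComparison <- function(config, swmResult = NULL, dataset = NULL) {
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  trainCfgs <- corpusConfigs(config, "train")
  evalCfgs <- corpusConfigs(config, "eval")
  trainIds <- vapply(trainCfgs, function(s) sprintf("scene-%d", s@seed), character(1))
  evalIds <- vapply(evalCfgs, function(s) sprintf("scene-%d", s@seed), character(1))
  if (length(intersect(trainIds, evalIds)))
    stop("evaluation scenes overlap the training corpus")

  if (is.null(swmResult)) {
    if (is.null(dataset)) {
      samples <- assembleBalancedDataset(trainCfgs, config@nPerClass,
                                         seed = deriveSeed(config@globalSeed, "windows"))
      dataset <- splitDataset(samples, config@trainFraction,
                              seed = deriveSeed(config@globalSeed, "split"))
    }
    message("[compare] training sliding-window classifier")
    swmResult <- trainPatchClassifier(buildPatchClassifier(config@grid[[1]]), dataset)
  }

  det <- config@detector
  backend <- if (is.null(det$backend)) "segmenter" else det$backend
  segmenter <- NULL
  if (backend == "segmenter") {
    message("[compare] training instance segmenter on ", length(trainCfgs), " pair(s)")
    pairs <- lapply(trainCfgs, function(s) sceneToTrainingPair(generateScene(s)))
    segmenter <- trainInstanceSegmenter(pairs,
                                        epochs = if (is.null(det$epochs)) 10L else det$epochs,
                                        seed = deriveSeed(config@globalSeed, "detector"))
  }

  message("[compare] evaluating both backends on ", length(evalCfgs), " scene(s)")
  swmMatches <- list(); instMatches <- list()
  for (i in seq_along(evalCfgs)) {
    scene <- generateScene(evalCfgs[[i]])
    pmap <- scoreImage(swmResult, scene@image, sourceId = scene@id)
    swmMatches[[i]] <- matchDetections(windowDetections(pmap, config@yellowThreshold),
                                       scene, mode = "window")
    dset <- if (backend == "oracle") {
      oracleDetect(scene@image, sourceId = scene@id)
    } else {
      detectNuclei(segmenter, scene@image,
                   scoreThreshold = if (is.null(det$scoreThreshold)) 0.5 else det$scoreThreshold,
                   nmsThreshold = if (is.null(det$nmsThreshold)) 0.5 else det$nmsThreshold,
                   minArea = if (is.null(det$minArea)) 20L else det$minArea,
                   sourceId = scene@id)
    }
    instMatches[[i]] <- matchDetections(dset, scene, mode = "instance")
  }
  swmMatch <- combineMatchResults(swmMatches)
  instanceMatch <- combineMatchResults(instMatches)
  table <- compareBackends(swmMatch, instanceMatch,
                           names = c("Sliding window",
                                     if (backend == "oracle") "Hue oracle" else "Pixel segmenter"))
  paths <- list(comparison = file.path(config@outputDir, "comparison.csv"))
  utils::write.csv(table, paths$comparison, row.names = FALSE)
  jsonlite::write_json(provenance(config, list(stage = "comparison", backend = backend)),
                       file.path(config@outputDir, "comparison_provenance.json"),
                       auto_unbox = TRUE)
  list(table = table, swmMatch = swmMatch, instanceMatch = instanceMatch,
       segmenter = segmenter, paths = paths)
}
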