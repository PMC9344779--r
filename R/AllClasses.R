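# S4 class definitions for the whole package. Conventions:
#  * image arrays are numeric H x W x 3 in [0, 1], indexed (row, col, channel)
#  * masks are logical matrices cropped to a bounding box
#  * boxes and window origins are 0-based; boxes are half-open
#    (row0, col0, row1, col1)

# ---- synthetic scenes ------------------------------------------------------

#' SceneConfig: parameters of one synthetic cytology field
#'
#' Describes a Papanicolaou-like liquid-based cytology field: sparse,
#' non-overlapping cells whose nuclei are rotated ellipses surrounded by a
#' paler cytoplasm halo. Basal-lineage cells stain blue (hue band
#' `[0.55, 0.72]`), superficial-lineage cells red/orange (hue near 0).
#'
#' @slot nBlue,nRed number of blue- / red-lineage cells.
#' @slot imageSize integer `(H, W)` in pixels; default `1024 x 1280`.
#' @slot nucleusRadiusRange range (px) the two nucleus semi-axes are drawn
#'   from, uniformly.
#' @slot ncRatioRange nucleus-to-cytoplasm area ratio range in `(0, 1]`;
#'   the cytoplasm ellipse is the nucleus scaled by `1/sqrt(nc)`.
#' @slot debrisDensity expected debris blobs per megapixel (Poisson).
#' @slot overlapFraction `[0, 1]`; 0 keeps all cell (cytoplasm) footprints
#'   disjoint, larger values progressively relax the placement separation.
#' @slot stainNoiseSd standard deviation of i.i.d. Gaussian intensity noise
#'   added to each RGB channel.
#' @slot seed RNG seed; generation is a pure function of (config, seed).
#' @exportClass SceneConfig
setClass("SceneConfig", representation(
  nBlue = "integer", nRed = "integer", imageSize = "integer",
  nucleusRadiusRange = "numeric", ncRatioRange = "numeric",
  debrisDensity = "numeric", overlapFraction = "numeric",
  stainNoiseSd = "numeric", seed = "integer"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nBlue < 0L || object@nRed < 0L) msg <- c(msg, "cell counts must be >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers (H, W)")
  rr <- object@nucleusRadiusRange
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 3)
    msg <- c(msg, "nucleusRadiusRange must be increasing and >= 3 px")
  nc <- object@ncRatioRange
  if (length(nc) != 2L || nc[1] > nc[2] || nc[1] <= 0 || nc[2] > 1)
    msg <- c(msg, "ncRatioRange must lie in (0, 1] and be non-decreasing")
  if (object@debrisDensity < 0) msg <- c(msg, "debrisDensity must be >= 0")
  if (object@overlapFraction < 0 || object@overlapFraction > 1)
    msg <- c(msg, "overlapFraction must be in [0, 1]")
  if (object@stainNoiseSd < 0) msg <- c(msg, "stainNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NucleusInstance: one ground-truth nucleus
#'
#' @slot id instance identifier (>= 1, unique within a scene).
#' @slot lineage `"blue"` (basal) or `"red"` (superficial).
#' @slot center `(row, col)` in pixels, 0-based.
#' @slot semiAxes ellipse semi-axes `(a, b)` in pixels.
#' @slot rotation radians.
#' @slot box bounding box of the mask, 0-based half-open.
#' @slot mask logical matrix cropped to `box`.
#' @exportClass NucleusInstance
setClass("NucleusInstance", representation(
  id = "integer", lineage = "character", center = "numeric",
  semiAxes = "numeric", rotation = "numeric",
  box = "integer", mask = "matrix"
))

setValidity("NucleusInstance", function(object) {
  msg <- character()
  if (object@id < 1L) msg <- c(msg, "id must be >= 1")
  if (!object@lineage %in% c("blue", "red")) msg <- c(msg, "lineage must be 'blue' or 'red'")
  if (length(object@box) != 4L || object@box[3] <= object@box[1] || object@box[4] <= object@box[2])
    msg <- c(msg, "box must be half-open (row0, col0, row1, col1) with positive extent")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (nrow(object@mask) != object@box[3] - object@box[1] ||
      ncol(object@mask) != object@box[4] - object@box[2])
    msg <- c(msg, "mask dimensions must match box extent")
  if (sum(object@mask) < 20L) msg <- c(msg, "mask area must be >= 20 px")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a generated image plus exact ground truth
#'
#' @slot image numeric `H x W x 3` RGB array in `[0, 1]`.
#' @slot instances list of [NucleusInstance-class] objects.
#' @slot debrisCount number of debris blobs drawn.
#' @slot seed seed the scene was generated with.
#' @slot config the [SceneConfig-class] used.
#' @slot id character scene identifier.
#' @exportClass SyntheticScene
setClass("SyntheticScene", representation(
  image = "array", instances = "list", debrisCount = "integer",
  seed = "integer", config = "SceneConfig", id = "character"
))

setValidity("SyntheticScene", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
  for (inst in object@instances) {
    if (!is(inst, "NucleusInstance")) return("instances must be NucleusInstance objects")
    if (inst@box[1] < 0L || inst@box[2] < 0L || inst@box[3] > d[1] || inst@box[4] > d[2])
      return(sprintf("instance %d mask exceeds image bounds", inst@id))
  }
  TRUE
})

# ---- sliding-window datasets ----------------------------------------------

#' WindowSet: a batch of 96x96 labelled window samples
#'
#' Columnar container: patches are stacked in a 4-d array and per-window
#' metadata lives in `info` (sourceId, row0, col0, label, coveredIds).
#' `label` is `"nucleus"` iff `coveredIds` is non-empty.
#'
#' @slot patches numeric array `window x window x 3 x n`.
#' @slot info data.frame with columns `sourceId`, `row0`, `col0`, `label`
#'   and list-column `coveredIds`.
#' @slot window window side in pixels.
#' @exportClass WindowSet
setClass("WindowSet", representation(
  patches = "array", info = "data.frame", window = "integer"
))

setValidity("WindowSet", function(object) {
  d <- dim(object@patches)
  n <- nrow(object@info)
  if (length(d) != 4L || d[1] != object@window || d[2] != object@window || d[3] != 3L)
    return("patches must be window x window x 3 x n")
  if (d[4] != n) return("patch count must match info rows")
  need <- c("sourceId", "row0", "col0", "label", "coveredIds")
  if (!all(need %in% names(object@info))) return("info is missing required columns")
  lab <- object@info$label
  hasIds <- vapply(object@info$coveredIds, length, 1L) > 0L
  if (n > 0L && !all((lab == "nucleus") == hasIds))
    return("label must be 'nucleus' exactly when coveredIds is non-empty")
  TRUE
})

#' WindowDataset: stratified train/test split of window samples
#'
#' @slot train,test [WindowSet-class] objects, disjoint by
#'   `(sourceId, origin)`.
#' @slot splitSeed seed used for the split.
#' @slot classCounts integer matrix, labels x splits.
#' @exportClass WindowDataset
setClass("WindowDataset", representation(
  train = "WindowSet", test = "WindowSet",
  splitSeed = "integer", classCounts = "matrix"
))

# ---- patch classifier ------------------------------------------------------

#' PatchClassifierConfig: one configuration-grid cell
#'
#' @slot activation `"ReLU"` or `"Sigmoid"` (hidden activations).
#' @slot epochs training epochs (>= 1).
#' @slot nLayers counted network depth; supported depths are 18 and 24,
#'   counting every convolution, activation, pooling, dropout, affine and
#'   softmax layer.
#' @slot dropoutRate dropout probability in `[0, 1)`.
#' @slot learningSeed seed for weight init and batch shuffling.
#' @slot batchSize minibatch size.
#' @slot learningRate ADAM step size.
#' @exportClass PatchClassifierConfig
setClass("PatchClassifierConfig", representation(
  activation = "character", epochs = "integer", nLayers = "integer",
  dropoutRate = "numeric", learningSeed = "integer",
  batchSize = "integer", learningRate = "numeric"
))

setValidity("PatchClassifierConfig", function(object) {
  msg <- character()
  if (!object@activation %in% c("ReLU", "Sigmoid"))
    msg <- c(msg, "activation must be 'ReLU' or 'Sigmoid'")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (!object@nLayers %in% supportedDepths())
    msg <- c(msg, paste0("nLayers must be one of: ",
                         paste(supportedDepths(), collapse = ", ")))
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' PatchClassifier: a (possibly trained) 96x96 two-class CNN
#'
#' @slot config the [PatchClassifierConfig-class].
#' @slot layers internal layer list (weights live here).
#' @slot inputSize input patch side in pixels.
#' @slot trained logical.
#' @exportClass PatchClassifier
setClass("PatchClassifier", representation(
  config = "PatchClassifierConfig", layers = "list",
  inputSize = "integer", trained = "logical"
))

#' TrainResult: fitted outcome of one grid configuration
#'
#' @slot config configuration trained.
#' @slot classifier trained [PatchClassifier-class].
#' @slot trainLoss,trainAccuracy,testLoss,testAccuracy final metrics
#'   (full evaluation passes, dropout off).
#' @slot history data.frame with one row per epoch
#'   (`epoch`, `trainLoss`, `trainAccuracy`, `testLoss`, `testAccuracy`).
#' @exportClass TrainResult
setClass("TrainResult", representation(
  config = "PatchClassifierConfig", classifier = "PatchClassifier",
  trainLoss = "numeric", trainAccuracy = "numeric",
  testLoss = "numeric", testAccuracy = "numeric",
  history = "data.frame"
))

setValidity("TrainResult", function(object) {
  acc <- c(object@trainAccuracy, object@testAccuracy)
  if (any(acc < 0 | acc > 1)) return("accuracies must lie in [0, 1]")
  if (nrow(object@history) != object@config@epochs)
    return("history must have one row per epoch")
  TRUE
})

#' ProbabilityMap: per-window nucleus probabilities over one image
#'
#' @slot map data.frame with `row0`, `col0`, `prob`.
#' @slot window window side in pixels.
#' @slot imageSize `(H, W)` of the scored image.
#' @slot sourceId image identifier.
#' @exportClass ProbabilityMap
setClass("ProbabilityMap", representation(
  map = "data.frame", window = "integer",
  imageSize = "integer", sourceId = "character"
))

setValidity("ProbabilityMap", function(object) {
  p <- object@map$prob
  if (is.null(p) || any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})

# ---- instance detection ----------------------------------------------------

#' Detection: one scored region proposal
#'
#' @slot box 0-based half-open `(row0, col0, row1, col1)`.
#' @slot mask logical matrix cropped to `box`.
#' @slot score detection confidence in `[0, 1]`.
#' @slot predictedClass label, `"nucleus"` for the single foreground class.
#' @exportClass Detection
setClass("Detection", representation(
  box = "integer", mask = "matrix", score = "numeric", predictedClass = "character"
))

setValidity("Detection", function(object) {
  if (object@score < 0 || object@score > 1) return("score must be in [0, 1]")
  if (nrow(object@mask) != object@box[3] - object@box[1] ||
      ncol(object@mask) != object@box[4] - object@box[2])
    return("mask must be cropped exactly to box")
  TRUE
})

#' DetectionSet: detector output for one image
#'
#' @slot detections list of [Detection-class].
#' @slot sourceId image identifier.
#' @slot backend name of the producing backend.
#' @slot scoreThreshold,nmsThreshold thresholds the set was filtered with.
#' @exportClass DetectionSet
setClass("DetectionSet", representation(
  detections = "list", sourceId = "character", backend = "character",
  scoreThreshold = "numeric", nmsThreshold = "numeric"
))

setValidity("DetectionSet", function(object) {
  for (d in object@detections) {
    if (!is(d, "Detection")) return("detections must be Detection objects")
    if (d@score < object@scoreThreshold) return("retained detections must satisfy scoreThreshold")
  }
  TRUE
})

#' MaskTrainingPair: an image with its instance masks
#'
#' @slot image RGB array.
#' @slot labelMask integer matrix, 0 background, instance id elsewhere.
#' @slot classTag provenance tag (e.g. cytology class) carried as metadata.
#' @exportClass MaskTrainingPair
setClass("MaskTrainingPair", representation(
  image = "array", labelMask = "matrix", classTag = "character"
))

#' InstanceSegmenter: trainable pixel-classifier instance detector
#'
#' A logistic colour model over per-pixel features, trained with ADAM on
#' image + mask pairs; inference thresholds the per-pixel nucleus
#' probability and proposes connected components as scored instances.
#'
#' @slot weights numeric feature weights (first element is the intercept).
#' @slot history data.frame of per-epoch `trainLoss` / `valLoss`.
#' @slot trained logical.
#' @slot params list of training parameters (pixel threshold etc.).
#' @exportClass InstanceSegmenter
setClass("InstanceSegmenter", representation(
  weights = "numeric", history = "data.frame", trained = "logical", params = "list"
))

# ---- evaluation ------------------------------------------------------------

#' MatchResult: matched-region accounting for one or more images
#'
#' Raw counts behind the four comparison criteria: `D` detections, `B`
#' background (unmatched) detections, `N` ground-truth blue nuclei, `U`
#' total undetected expected regions, `M = D - B` matched detections.
#'
#' @slot nDetections,nBackground,nNuclei,nUndetected,nMatched the counts.
#' @slot perNucleus data.frame (per nucleus: `sourceId`, `id`, `expected`,
#'   `detected`, `undetected`, `regions`); may be empty when the object is
#'   built from bare counts.
#' @slot sourceIds image identifiers covered (empty for bare counts).
#' @slot mode `"instance"`, `"window"` or `"counts"`.
#' @exportClass MatchResult
setClass("MatchResult", representation(
  nDetections = "integer", nBackground = "integer", nNuclei = "integer",
  nUndetected = "integer", nMatched = "integer",
  perNucleus = "data.frame", sourceIds = "character", mode = "character"
))

setValidity("MatchResult", function(object) {
  msg <- character()
  if (object@nBackground > object@nDetections) msg <- c(msg, "B must be <= D")
  if (object@nMatched > object@nDetections) msg <- c(msg, "M must be <= D")
  if (object@nUndetected < 0L) msg <- c(msg, "U must be >= 0")
  if (object@nBackground + object@nMatched != object@nDetections)
    msg <- c(msg, "B + M must equal D")
  if (length(msg)) msg else TRUE
})

#' ComparisonMetrics: the four comparison criteria
#'
#' @slot nDetections number of detections.
#' @slot backgroundFraction fraction of detections matching no nucleus
#'   (`B/D`; 0 when `D = 0` by convention).
#' @slot avgUndetected average undetected regions per nucleus (`U/N`).
#' @slot avgRegions average detected regions per nucleus (`M/N`).
#' @slot counts named integer vector `(D, B, N, U, M)`.
#' @slot decimals rounding used (half-up).
#' @exportClass ComparisonMetrics
setClass("ComparisonMetrics", representation(
  nDetections = "integer", backgroundFraction = "numeric",
  avgUndetected = "numeric", avgRegions = "numeric",
  counts = "integer", decimals = "integer"
))

# ---- pipeline --------------------------------------------------------------

#' RunConfig: full desk-scale experiment configuration
#'
#' @slot scene [SceneConfig-class] template for generated fields.
#' @slot nTrainScenes,nEvalScenes corpus sizes.
#' @slot nPerClass balanced window samples per label.
#' @slot trainFraction train split fraction.
#' @slot grid list of [PatchClassifierConfig-class] to run.
#' @slot overfitGap overlearning flag threshold on train - test accuracy.
#' @slot redThreshold,yellowThreshold overlay thresholds.
#' @slot detector list of instance-backend options.
#' @slot globalSeed master seed; all stage seeds derive from it.
#' @slot outputDir artifact directory.
#' @exportClass RunConfig
setClass("RunConfig", representation(
  scene = "SceneConfig", nTrainScenes = "integer", nEvalScenes = "integer",
  nPerClass = "integer", trainFraction = "numeric", grid = "list",
  overfitGap = "numeric", redThreshold = "numeric", yellowThreshold = "numeric",
  detector = "list", globalSeed = "integer", outputDir = "character"
))
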