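#' @import methods
NULL

#' @rdname sceneImage
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname sceneInstances
#' @export
setGeneric("sceneInstances", function(x) standardGeneric("sceneInstances"))

#' @rdname instanceMask
#' @export
setGeneric("instanceMask", function(x, id, full = TRUE) standardGeneric("instanceMask"))

#' @rdname labelMask
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @rdname lineages
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname windowInfo
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @rdname windowPatch
#' @export
setGeneric("windowPatch", function(x, i) standardGeneric("windowPatch"))

#' @rdname classCounts
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname trainSet
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @rdname testSet
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname detections
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname detectionScores
#' @export
setGeneric("detectionScores", function(x) standardGeneric("detectionScores"))

#' @rdname detectionBoxes
#' @export
setGeneric("detectionBoxes", function(x) standardGeneric("detectionBoxes"))

#' @rdname trainingHistory
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Detect nucleus instances in an image
#'
#' @param object a trained detector handle.
#' @param image RGB array `H x W x 3` in `[0, 1]`.
#' @param ... backend options such as `scoreThreshold`, `nmsThreshold`,
#'   `minArea`, `sourceId`.
#' @return a [DetectionSet-class].
#' @export
setGeneric("detectNuclei", function(object, image, ...) standardGeneric("detectNuclei"))
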