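# Instance-level nucleus detection. Two backends share the DetectionSet
# contract:
#  * oracleDetect(): classical hue-threshold reference detector (blue band
#    + saturation gate + connected components), used as the brute-force
#    reference in tests and as a perfect-detector baseline.
#  * InstanceSegmenter: a trainable pixel-classifier segmenter — a logistic
#    colour model over per-pixel features fitted by ADAM on image + mask
#    pairs, followed by thresholded connected components, per-component
#    scoring and non-maximum suppression.

#' Build a Detection object
#'
#' @param mask full-image logical matrix, or cropped mask with `box`.
#' @param box 0-based half-open bounding box when `mask` is cropped.
#' @param score confidence in `[0, 1]`.
#' @param predictedClass class label.
#' @return a [Detection-class].
#' @export
detection <- function(mask, box = NULL, score = 1, predictedClass = "nucleus") {
  if (is.null(box)) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("detection mask is empty")
    r <- range(idx[, 1]); c <- range(idx[, 2])
    box <- c(r[1] - 1L, c[1] - 1L, r[2], c[2])
    mask <- mask[r[1]:r[2], c[1]:c[2], drop = FALSE]
  }
  new("Detection", box = as.integer(box), mask = mask,
      score = as.numeric(score), predictedClass = predictedClass)
}

newDetectionSet <- function(detections, sourceId = "image", backend = "unknown",
                            scoreThreshold = 0, nmsThreshold = 1) {
  new("DetectionSet", detections = detections, sourceId = sourceId,
      backend = backend, scoreThreshold = as.numeric(scoreThreshold),
      nmsThreshold = as.numeric(nmsThreshold))
}

#' Number of detections
#' @param x a [DetectionSet-class].
#' @export
setMethod("length", "DetectionSet", function(x) length(x@detections))

#' @rdname detections
#' @param x a [DetectionSet-class].
#' @export
setMethod("detections", "DetectionSet", function(x) x@detections)

#' @rdname detectionScores
#' @param x a [DetectionSet-class].
#' @export
setMethod("detectionScores", "DetectionSet", function(x)
  vapply(x@detections, function(d) d@score, numeric(1)))

#' @rdname detectionBoxes
#' @param x a [DetectionSet-class].
#' @export
setMethod("detectionBoxes", "DetectionSet", function(x) {
  if (!length(x@detections)) return(matrix(integer(), 0, 4,
                                           dimnames = list(NULL, c("row0", "col0", "row1", "col1"))))
  t(vapply(x@detections, function(d) d@box, integer(4))) |>
    `colnames<-`(c("row0", "col0", "row1", "col1"))
})

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet '%s' (%s backend): %d detections, score >= %.2f, NMS %.2f\n",
              object@sourceId, object@backend, length(object),
              object@scoreThreshold, object@nmsThreshold))
})

# Mask IoU of two detections (via box-intersection arithmetic).
detectionIoU <- function(a, b) {
  inter <- maskOverlap(a@mask, a@box, b@mask, b@box)
  if (inter == 0L) return(0)
  inter / (sum(a@mask) + sum(b@mask) - inter)
}

#' Greedy non-maximum suppression by mask IoU
#'
#' Keeps detections in decreasing score order, dropping any whose mask IoU
#' with an already-kept detection exceeds `nmsThreshold`. Idempotent.
#'
#' @param dets list of [Detection-class].
#' @param nmsThreshold IoU above which the lower-scoring detection is
#'   suppressed.
#' @return filtered list of detections.
#' @export
nmsFilter <- function(dets, nmsThreshold = 0.5) {
  if (length(dets) <= 1L) return(dets)
  ord <- order(-vapply(dets, function(d) d@score, numeric(1)))
  keepIdx <- integer()
  for (i in ord) {
    clash <- any(vapply(keepIdx, function(k) detectionIoU(dets[[i]], dets[[k]]) > nmsThreshold,
                        logical(1)))
    if (!clash) keepIdx <- c(keepIdx, i)
  }
  dets[sort(keepIdx)]
}

# Connected components of a logical matrix -> list of Detection objects.
componentsToDetections <- function(fg, scoreMap = NULL, minArea = 20L,
                                   predictedClass = "nucleus") {
  lab <- EBImage::bwlabel(fg)
  nLab <- max(lab)
  if (nLab == 0L) return(list())
  out <- list()
  idxAll <- which(lab > 0L)
  comp <- split(idxAll, lab[idxAll])
  nr <- nrow(fg)
  for (px in comp) {
    if (length(px) < minArea) next
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    r <- range(rows); c <- range(cols)
    box <- c(r[1] - 1L, c[1] - 1L, r[2], c[2])
    m <- matrix(FALSE, r[2] - r[1] + 1L, c[2] - c[1] + 1L)
    m[cbind(rows - r[1] + 1L, cols - c[1] + 1L)] <- TRUE
    score <- if (is.null(scoreMap)) 1 else mean(scoreMap[px])
    out[[length(out) + 1L]] <- detection(m, box, score = score,
                                         predictedClass = predictedClass)
  }
  out
}

#' Classical hue-threshold reference detector
#'
#' Thresholds pixels whose hue lies in the blue band and whose saturation
#' clears `minSaturation` (background and pale cytoplasm are nearly
#' unsaturated), then proposes each connected component of at least
#' `minArea` pixels as a detection with score 1.
#'
#' @param image RGB array `H x W x 3` in `[0, 1]`.
#' @param blueHueBand hue interval treated as blue-stained.
#' @param minArea minimum component area in pixels.
#' @param minSaturation saturation gate.
#' @param sourceId image identifier.
#' @return a [DetectionSet-class] (backend `"oracle"`).
#' @export
oracleDetect <- function(image, blueHueBand = stainHueBands()$blue,
                         minArea = 20L, minSaturation = 0.3,
                         sourceId = "image") {
  hsv <- rgbToHsv(image)
  fg <- hueInBand(hsv$h, blueHueBand) & hsv$s >= minSaturation
  dets <- componentsToDetections(fg, minArea = minArea)
  newDetectionSet(dets, sourceId = sourceId, backend = "oracle",
                  scoreThreshold = 0, nmsThreshold = 1)
}

# ---- trainable pixel-classifier backend ------------------------------------

#' Create a mask training pair
#'
#' @param image RGB array.
#' @param labelMask integer matrix (0 background, instance id elsewhere).
#' @param classTag provenance tag carried as metadata (e.g. a cytology
#'   class label); not used by the single-foreground-class detector.
#' @return a [MaskTrainingPair-class].
#' @export
maskTrainingPair <- function(image, labelMask, classTag = "II") {
  stopifnot(all(dim(image)[1:2] == dim(labelMask)))
  new("MaskTrainingPair", image = image,
      labelMask = matrix(as.integer(labelMask), nrow(labelMask)),
      classTag = classTag)
}

#' Training pair from a synthetic scene
#'
#' Uses only blue-lineage instances as foreground, matching the detection
#' target (basal-lineage nuclei).
#'
#' @param scene a [SyntheticScene-class].
#' @param classTag provenance tag.
#' @return a [MaskTrainingPair-class].
#' @export
sceneToTrainingPair <- function(scene, classTag = "II") {
  d <- dim(scene@image)
  lab <- matrix(0L, d[1], d[2])
  for (inst in scene@instances) {
    if (inst@lineage != "blue") next
    rows <- (inst@box[1] + 1L):inst@box[3]
    cols <- (inst@box[2] + 1L):inst@box[4]
    sub <- lab[rows, cols]
    sub[inst@mask] <- inst@id
    lab[rows, cols] <- sub
  }
  maskTrainingPair(scene@image, lab, classTag)
}

# Per-pixel feature matrix: intercept, RGB, chroma and opponent-colour
# contrasts, including explicit blueness / redness (channel excess over
# the other two), which separate the two stain lineages linearly. Rows
# are pixels.
pixelFeatures <- function(image) {
  r <- as.numeric(image[, , 1]); g <- as.numeric(image[, , 2])
  b <- as.numeric(image[, , 3])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  cbind(1, r, g, b, mx - mn, b - pmax(r, g), r - pmax(g, b), g - b)
}

sigmoidv <- function(z) 1 / (1 + exp(-z))

#' Train the pixel-classifier instance segmenter
#'
#' Fits a logistic colour model (per-pixel nucleus probability) with ADAM
#' on pixels sampled from image + mask pairs: each epoch draws a balanced
#' pixel sample per image (foreground vs background) and takes one
#' full-sample gradient step per image. A fixed held-out pixel set tracks
#' validation loss. Deterministic under `seed`.
#'
#' @param pairs list of [MaskTrainingPair-class] (at least one pair must
#'   contain a mask; mask-free images act as pure negatives).
#' @param epochs passes over the pair list.
#' @param seed RNG seed.
#' @param pixelsPerImage pixel sample size per image per epoch.
#' @param learningRate ADAM step size.
#' @return a trained [InstanceSegmenter-class] with per-epoch
#'   `trainLoss` / `valLoss` history of length `epochs`.
#' @export
trainInstanceSegmenter <- function(pairs, epochs = 10L, seed = 1L,
                                   pixelsPerImage = 4000L, learningRate = 0.05) {
  if (!length(pairs)) stop("no training pairs supplied")
  if (!any(vapply(pairs, function(p) any(p@labelMask > 0L), logical(1))))
    stop("at least one training pair must contain an instance mask")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")

  withSeed(seed, {
    # fixed validation pixel set drawn once from every pair
    valX <- list(); valY <- list()
    for (p in pairs) {
      Xi <- pixelFeatures(p@image)
      yi <- as.numeric(p@labelMask > 0L)
      take <- sample.int(length(yi), min(2000L, length(yi)))
      valX[[length(valX) + 1L]] <- Xi[take, , drop = FALSE]
      valY[[length(valY) + 1L]] <- yi[take]
    }
    valX <- do.call(rbind, valX); valY <- unlist(valY)

    w <- numeric(ncol(valX))
    m <- w; v <- w; t <- 0L
    bce <- function(X, y, w) {
      p <- sigmoidv(as.numeric(X %*% w))
      -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
    }
    hist <- vector("list", epochs)
    for (epoch in seq_len(epochs)) {
      losses <- numeric(0)
      for (p in pairs) {
        yi <- as.numeric(p@labelMask > 0L)
        fgIdx <- which(yi > 0); bgIdx <- which(yi == 0)
        nHalf <- min(pixelsPerImage %/% 2L, length(fgIdx))
        takeFg <- if (length(fgIdx)) sample(fgIdx, max(nHalf, 1L)) else integer()
        # background half is itself stratified: uniformly drawn pixels plus
        # strongly stained (high-chroma) non-target pixels — red-lineage
        # nuclei are rare by pixel count and would otherwise sit on the
        # decision boundary
        img <- p@image
        chroma <- pmax(img[, , 1], img[, , 2], img[, , 3]) -
          pmin(img[, , 1], img[, , 2], img[, , 3])
        bgHard <- bgIdx[chroma[bgIdx] > 0.25]
        nBg <- min(pixelsPerImage - length(takeFg), length(bgIdx))
        nHard <- min(nBg %/% 2L, length(bgHard))
        takeBg <- c(if (nHard > 0L) sample(bgHard, nHard) else integer(),
                    sample(bgIdx, nBg - nHard))
        take <- c(takeFg, takeBg)
        Xi <- pixelFeatures(p@image)[take, , drop = FALSE]
        ysub <- yi[take]
        pr <- sigmoidv(as.numeric(Xi %*% w))
        losses <- c(losses, -mean(ysub * log(pr + 1e-12) + (1 - ysub) * log(1 - pr + 1e-12)))
        grad <- as.numeric(crossprod(Xi, pr - ysub)) / length(ysub)
        t <- t + 1L
        m <- 0.9 * m + 0.1 * grad
        v <- 0.999 * v + 0.001 * grad^2
        w <- w - learningRate * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = mean(losses),
                                  valLoss = bce(valX, valY, w))
    }
    new("InstanceSegmenter", weights = w, history = do.call(rbind, hist),
        trained = TRUE,
        params = list(epochs = epochs, seed = as.integer(seed),
                      pixelsPerImage = as.integer(pixelsPerImage),
                      learningRate = learningRate, pixelThreshold = 0.5))
  })
}

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "InstanceSegmenter", function(x) x@history)

setMethod("show", "InstanceSegmenter", function(object) {
  h <- object@history
  cat(sprintf("InstanceSegmenter: %s, %d epochs (val loss %.4f -> %.4f)\n",
              if (object@trained) "trained" else "untrained",
              nrow(h), h$valLoss[1], h$valLoss[nrow(h)]))
})

#' Per-pixel nucleus probability map
#'
#' @param segmenter a trained [InstanceSegmenter-class].
#' @param image RGB array.
#' @return numeric matrix `H x W` of probabilities.
#' @export
pixelProbabilities <- function(segmenter, image) {
  if (!segmenter@trained) stop("segmenter has not been trained")
  d <- dim(image)
  matrix(sigmoidv(as.numeric(pixelFeatures(image) %*% segmenter@weights)),
         d[1], d[2])
}

#' @describeIn detectNuclei thresholded connected components of the pixel
#'   probability map, scored by mean component probability, filtered by
#'   `scoreThreshold` and greedily suppressed at `nmsThreshold` mask IoU.
#'   Raising `scoreThreshold` never increases the detection count.
#' @param scoreThreshold minimum detection score retained.
#' @param nmsThreshold mask-IoU suppression threshold.
#' @param minArea minimum component area (px).
#' @param sourceId image identifier.
#' @export
setMethod("detectNuclei", "InstanceSegmenter",
          function(object, image, scoreThreshold = 0.5, nmsThreshold = 0.5,
                   minArea = 20L, sourceId = "image") {
  if (!object@trained) stop("segmenter has not been trained")
  prob <- pixelProbabilities(object, image)
  fg <- prob > object@params$pixelThreshold
  dets <- componentsToDetections(fg, scoreMap = prob, minArea = minArea)
  dets <- Filter(function(d) d@score >= scoreThreshold, dets)
  dets <- nmsFilter(dets, nmsThreshold)
  newDetectionSet(dets, sourceId = sourceId, backend = "pixelSegmenter",
                  scoreThreshold = scoreThreshold, nmsThreshold = nmsThreshold)
})

#' Convert a window probability map to window-level detections
#'
#' Every window with nucleus probability strictly above `threshold` (the
#' yellow overlay band by default) becomes one full-window detection whose
#' score is the window probability.
#'
#' @param pmap a [ProbabilityMap-class].
#' @param threshold strict probability cutoff.
#' @return a [DetectionSet-class] (backend `"swm"`).
#' @export
windowDetections <- function(pmap, threshold = 0.5) {
  w <- pmap@window
  sel <- which(pmap@map$prob > threshold)
  dets <- lapply(sel, function(i) {
    r <- pmap@map$row0[i]; c <- pmap@map$col0[i]
    detection(matrix(TRUE, w, w), box = c(r, c, r + w, c + w),
              score = pmap@map$prob[i])
  })
  newDetectionSet(dets, sourceId = pmap@sourceId, backend = "swm",
                  scoreThreshold = threshold, nmsThreshold = 1)
}

#' Export detections as COCO-style results JSON and a labelled mask PNG
#'
#' @param dset a [DetectionSet-class].
#' @param imageSize `(H, W)` of the source image.
#' @param directory output directory.
#' @return (invisibly) character vector of written paths.
#' @export
exportDetections <- function(dset, imageSize, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_along(dset@detections), function(i) {
    d <- dset@detections[[i]]
    list(image_id = dset@sourceId, category_id = 1L,
         bbox = c(d@box[2], d@box[1], d@box[4] - d@box[2], d@box[3] - d@box[1]),
         score = d@score)
  })
  jsonPath <- file.path(directory, paste0(dset@sourceId, "_detections.json"))
  jsonlite::write_json(res, jsonPath, auto_unbox = TRUE, digits = NA)
  lab <- matrix(0L, imageSize[1], imageSize[2])
  for (i in seq_along(dset@detections)) {
    d <- dset@detections[[i]]
    rows <- (d@box[1] + 1L):d@box[3]; cols <- (d@box[2] + 1L):d@box[4]
    sub <- lab[rows, cols]
    sub[d@mask] <- i
    lab[rows, cols] <- sub
  }
  pngPath <- file.path(directory, paste0(dset@sourceId, "_detections.png"))
  png::writePNG(lab / max(1L, max(lab)), pngPath)
  invisible(c(jsonPath, pngPath))
}
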