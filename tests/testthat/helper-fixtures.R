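# Shared fixtures: all synthetic, generated in code at test time.

# A small, quickly generated field.
smallSceneConfig <- function(seed, nBlue = 5L, nRed = 3L,
                             imageSize = c(288L, 384L), ...) {
  sceneConfig(nBlue = nBlue, nRed = nRed, imageSize = imageSize, seed = seed, ...)
}

smallScene <- function(seed, ...) generateScene(smallSceneConfig(seed, ...))

# Easy, high-contrast corpus for classifier tests.
easyScenes <- function(n, seedBase = 4000L, nBlue = 6L, nRed = 2L,
                       imageSize = c(288L, 384L)) {
  lapply(seq_len(n), function(i)
    generateScene(sceneConfig(nBlue = nBlue, nRed = nRed, imageSize = imageSize,
                              seed = seedBase + i)))
}

# Brute-force window labelling: full-raster pixel counting, independent of
# labelWindow()'s cropped-mask arithmetic.
bruteLabelWindow <- function(origin, scene, coverageThreshold = 0.5, window = 96L) {
  ids <- integer()
  rows <- (origin[1] + 1L):(origin[1] + window)
  cols <- (origin[2] + 1L):(origin[2] + window)
  for (inst in sceneInstances(scene)) {
    if (inst@lineage != "blue") next
    m <- instanceMask(scene, inst@id)
    if (sum(m[rows, cols]) / sum(m) > coverageThreshold) ids <- c(ids, inst@id)
  }
  list(label = if (length(ids)) "nucleus" else "non_nucleus", coveredIds = ids)
}

# Brute-force detection matching: all detection x nucleus pairs on full
# rasters, same criterion as matchDetections(mode = "instance").
bruteMatchInstance <- function(dset, scene, minOverlap = 0.25) {
  d <- dim(sceneImage(scene))
  blue <- Filter(function(i) i@lineage == "blue", sceneInstances(scene))
  gtMasks <- lapply(blue, function(i) instanceMask(scene, i@id))
  dets <- detections(dset)
  assigned <- rep(NA_integer_, length(dets))
  for (j in seq_along(dets)) {
    dm <- matrix(FALSE, d[1], d[2])
    bx <- dets[[j]]@box
    dm[(bx[1] + 1L):bx[3], (bx[2] + 1L):bx[4]] <- dets[[j]]@mask
    best <- NA_integer_; bestOv <- -1
    for (k in seq_along(blue)) {
      ov <- sum(dm & gtMasks[[k]])
      ctr <- round(blue[[k]]@center)
      hit <- (ov / sum(dm) >= minOverlap) ||
        dm[ctr[1] + 1L, ctr[2] + 1L]
      if (hit && ov > bestOv) { bestOv <- ov; best <- k }
    }
    assigned[j] <- best
  }
  regions <- tabulate(assigned[!is.na(assigned)], nbins = length(blue))
  list(D = length(dets), B = sum(is.na(assigned)),
       N = length(blue), U = sum(regions == 0L), M = sum(!is.na(assigned)),
       regions = regions)
}

# Hue-threshold patch classifier: the independent reference the CNN is
# checked against on easy corpora.
huePatchOracle <- function(patches, blueBand = stainHueBands()$blue,
                           minPixels = 100L) {
  n <- dim(patches)[4]
  vapply(seq_len(n), function(i) {
    p <- patches[, , , i]
    hsv <- rgbToHsv(p)
    blue <- sum(hsv$h >= blueBand[1] & hsv$h <= blueBand[2] & hsv$s >= 0.3)
    if (blue >= minPixels) "nucleus" else "non_nucleus"
  }, character(1))
}

# Hand-built scene: one rectangular blue "nucleus" mask whose window
# coverage can be controlled exactly.
rectangleScene <- function(maskRows, maskCols, imageSize = c(192L, 192L),
                           extraPixel = NULL) {
  m <- matrix(FALSE, imageSize[1], imageSize[2])
  m[maskRows, maskCols] <- TRUE
  if (!is.null(extraPixel)) m[extraPixel[1], extraPixel[2]] <- TRUE
  img <- array(0.94, dim = c(imageSize, 3L))
  img[, , 1][m] <- 0.2; img[, , 2][m] <- 0.3; img[, , 3][m] <- 0.8
  syntheticScene(img, list(nucleusInstance(1L, "blue", m)), id = "rect-scene")
}
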