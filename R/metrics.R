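# Matched-region evaluation: the four comparison criteria
#   (1) number of detections                      D
#   (2) fraction incorrectly detected from background  B / D
#   (3) average undetected nuclear regions per nucleus U / N
#   (4) average detected regions per nucleus           M / N
# computed from an explicit detection-to-nucleus matching. A detection is
# background iff it matches no blue-lineage ground-truth nucleus under the
# overlap criterion; every matched detection is assigned to its single
# best-overlapping nucleus, so B + M = D.

#' Build a MatchResult from bare counts
#'
#' For count-level arithmetic (e.g. reproducing a printed comparison table
#' from its raw fractions) without any matching.
#'
#' @param nDetections,nBackground,nNuclei,nUndetected total counts; the
#'   matched count is `nDetections - nBackground`.
#' @return a [MatchResult-class] with mode `"counts"`.
#' @export
matchResult <- function(nDetections, nBackground, nNuclei, nUndetected = 0L) {
  new("MatchResult", nDetections = as.integer(nDetections),
      nBackground = as.integer(nBackground), nNuclei = as.integer(nNuclei),
      nUndetected = as.integer(nUndetected),
      nMatched = as.integer(nDetections) - as.integer(nBackground),
      perNucleus = data.frame(), sourceIds = character(), mode = "counts")
}

# Does detection d match ground-truth instance g?
#  criterion "overlap": |det & gt| / |det| >= minOverlap OR the gt centroid
#    lies inside the detection mask (approximates visual matching);
#  criterion "iou": IoU >= iouThreshold (strict alternative).
detectionMatchesInstance <- function(det, inst, criterion, minOverlap, iouThreshold) {
  ov <- maskOverlap(det@mask, det@box, inst@mask, inst@box)
  if (criterion == "iou") {
    if (ov == 0L) return(FALSE)
    return(ov / (sum(det@mask) + sum(inst@mask) - ov) >= iouThreshold)
  }
  if (ov / sum(det@mask) >= minOverlap) return(TRUE)
  ctr <- round(inst@center)
  if (ctr[1] >= det@box[1] && ctr[1] < det@box[3] &&
      ctr[2] >= det@box[2] && ctr[2] < det@box[4]) {
    return(det@mask[ctr[1] - det@box[1] + 1L, ctr[2] - det@box[2] + 1L])
  }
  FALSE
}

#' Match detections against scene ground truth
#'
#' Every detection is classified as background (no blue-lineage nucleus
#' matches it) or assigned to its best-overlapping nucleus. Expected
#' regions per nucleus depend on the mode:
#' * `"instance"` — each nucleus is expected once; it is undetected when
#'   no detection is assigned to it.
#' * `"window"` — for window-level detections (see [windowDetections()]):
#'   a nucleus's expected regions are the grid windows positively labelled
#'   for it by [labelWindow()]; its undetected count is the number of
#'   those windows absent from the detection set.
#'
#' @param dset a [DetectionSet-class].
#' @param scene a [SyntheticScene-class] in the same coordinate frame.
#' @param mode `"instance"` or `"window"`.
#' @param criterion `"overlap"` (permissive: detection-mask overlap
#'   fraction or ground-truth centroid containment) or `"iou"`.
#' @param minOverlap overlap-fraction threshold for `"overlap"`.
#' @param iouThreshold IoU threshold for `"iou"`.
#' @param coverageThreshold,window labelling-rule parameters
#'   (`"window"` mode).
#' @return a [MatchResult-class].
#' @export
matchDetections <- function(dset, scene, mode = c("instance", "window"),
                            criterion = c("overlap", "iou"),
                            minOverlap = 0.25, iouThreshold = 0.5,
                            coverageThreshold = 0.5, window = 96L) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  d <- dim(scene@image)
  for (det in dset@detections) {
    if (det@box[1] < 0L || det@box[2] < 0L || det@box[3] > d[1] || det@box[4] > d[2])
      stop("detection box lies outside the scene image: coordinate frames disagree")
  }
  blue <- Filter(function(i) i@lineage == "blue", scene@instances)
  N <- length(blue)
  D <- length(dset@detections)
  assigned <- rep(NA_integer_, D)   # index into `blue`
  for (j in seq_len(D)) {
    det <- dset@detections[[j]]
    best <- NA_integer_; bestOv <- -1L
    for (k in seq_len(N)) {
      if (!detectionMatchesInstance(det, blue[[k]], criterion, minOverlap, iouThreshold))
        next
      ov <- maskOverlap(det@mask, det@box, blue[[k]]@mask, blue[[k]]@box)
      if (ov > bestOv) { bestOv <- ov; best <- k }
    }
    assigned[j] <- best
  }
  B <- sum(is.na(assigned))
  regions <- tabulate(assigned[!is.na(assigned)], nbins = N)

  if (mode == "instance") {
    expected <- rep(1L, N)
    detected <- as.integer(regions > 0L)
  } else {
    tl <- tileImage(scene@image, window = window, extract = FALSE)
    expected <- integer(N)
    detectedWindows <- vector("list", N)
    detKeys <- vapply(dset@detections, function(x) paste(x@box[1], x@box[2]),
                      character(1))
    for (i in seq_len(nrow(tl$origins))) {
      lw <- labelWindow(tl$origins[i, ], scene, coverageThreshold, window)
      for (id in lw$coveredIds) {
        k <- which(vapply(blue, function(b) b@id == id, logical(1)))
        expected[k] <- expected[k] + 1L
        if (paste(tl$origins[i, 1], tl$origins[i, 2]) %in% detKeys)
          detectedWindows[[k]] <- c(detectedWindows[[k]], i)
      }
    }
    detected <- vapply(detectedWindows, length, 1L)
  }
  undet <- pmax(0L, expected - detected)
  perNucleus <- data.frame(
    sourceId = rep(dset@sourceId, N),
    id = vapply(blue, function(b) b@id, integer(1)),
    expected = expected, detected = detected, undetected = undet,
    regions = regions)
  new("MatchResult", nDetections = D, nBackground = as.integer(B),
      nNuclei = as.integer(N), nUndetected = as.integer(sum(undet)),
      nMatched = as.integer(D - B), perNucleus = perNucleus,
      sourceIds = dset@sourceId, mode = mode)
}

#' Combine per-image match results
#'
#' Sums the counts (and concatenates per-nucleus tables) of results
#' computed with the same mode over different images.
#'
#' @param results list of [MatchResult-class].
#' @return a pooled [MatchResult-class].
#' @export
combineMatchResults <- function(results) {
  if (!length(results)) stop("no results to combine")
  modes <- unique(vapply(results, function(r) r@mode, character(1)))
  if (length(modes) > 1L) stop("cannot combine results of different modes")
  new("MatchResult",
      nDetections = sum(vapply(results, function(r) r@nDetections, 1L)),
      nBackground = sum(vapply(results, function(r) r@nBackground, 1L)),
      nNuclei = sum(vapply(results, function(r) r@nNuclei, 1L)),
      nUndetected = sum(vapply(results, function(r) r@nUndetected, 1L)),
      nMatched = sum(vapply(results, function(r) r@nMatched, 1L)),
      perNucleus = do.call(rbind, lapply(results, function(r) r@perNucleus)),
      sourceIds = unlist(lapply(results, function(r) r@sourceIds)),
      mode = modes)
}

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult (%s): D=%d, B=%d, N=%d, U=%d, M=%d over %d image(s)\n",
              object@mode, object@nDetections, object@nBackground,
              object@nNuclei, object@nUndetected, object@nMatched,
              max(1L, length(object@sourceIds))))
})

#' Compute the four comparison criteria
#'
#' `backgroundFraction = B/D` (0 when `D = 0` by convention),
#' `avgUndetected = U/N`, `avgRegions = M/N`, each rounded half-up to
#' `decimals` places.
#'
#' @param match a [MatchResult-class].
#' @param decimals decimal places (half-up rounding).
#' @return a [ComparisonMetrics-class].
#' @export
computeMetrics <- function(match, decimals = 4L) {
  D <- match@nDetections; B <- match@nBackground; N <- match@nNuclei
  U <- match@nUndetected; M <- match@nMatched
  if (N < 1L) stop("per-nucleus averages require at least one ground-truth nucleus")
  bf <- if (D == 0L) 0 else B / D
  new("ComparisonMetrics",
      nDetections = D,
      backgroundFraction = roundHalfUp(bf, decimals),
      avgUndetected = roundHalfUp(U / N, decimals),
      avgRegions = roundHalfUp(M / N, decimals),
      counts = c(D = D, B = B, N = N, U = U, M = M),
      decimals = as.integer(decimals))
}

setMethod("show", "ComparisonMetrics", function(object) {
  k <- object@counts
  cat(sprintf("ComparisonMetrics:\n  detections: %d\n  background fraction: %s (%d/%d)\n  avg undetected per nucleus: %s (%d/%d)\n  avg regions per nucleus: %s (%d/%d)\n",
              object@nDetections,
              format(object@backgroundFraction), k["B"], k["D"],
              format(object@avgUndetected), k["U"], k["N"],
              format(object@avgRegions), k["M"], k["N"]))
})

#' Metrics as a one-row data.frame
#' @param metrics a [ComparisonMetrics-class].
#' @return data.frame with the four criteria and the raw counts.
#' @export
metricsAsRow <- function(metrics) {
  k <- metrics@counts
  data.frame(nDetections = metrics@nDetections,
             backgroundFraction = metrics@backgroundFraction,
             avgUndetected = metrics@avgUndetected,
             avgRegions = metrics@avgRegions,
             D = k[["D"]], B = k[["B"]], N = k[["N"]], U = k[["U"]], M = k[["M"]])
}

#' Two-backend comparison table
#'
#' Mirrors the four-criterion layout: one row per criterion, one column
#' per backend, numeric cells formatted with their raw fractions in
#' parentheses.
#'
#' @param resultA,resultB [MatchResult-class] objects computed on the same
#'   image set (checked by source id when both carry ids).
#' @param names column names for the two backends.
#' @param decimals rounding for the formatted values.
#' @return data.frame with columns `criterion`, `<names[1]>`, `<names[2]>`
#'   and a `"numeric"` attribute holding the unformatted values.
#' @export
compareBackends <- function(resultA, resultB,
                            names = c("Sliding window", "Instance"),
                            decimals = 4L) {
  if (length(resultA@sourceIds) && length(resultB@sourceIds) &&
      !setequal(resultA@sourceIds, resultB@sourceIds))
    stop("the two results cover different image sets")
  fmtCol <- function(res) {
    m <- computeMetrics(res, decimals)
    k <- m@counts
    fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
    c(fmt(m@nDetections),
      sprintf("%s (%d/%d)", fmt(m@backgroundFraction), k["B"], k["D"]),
      sprintf("%s (%d/%d)", fmt(m@avgUndetected), k["U"], k["N"]),
      sprintf("%s (%d/%d)", fmt(m@avgRegions), k["M"], k["N"]))
  }
  numCol <- function(res) {
    m <- computeMetrics(res, decimals)
    c(m@nDetections, m@backgroundFraction, m@avgUndetected, m@avgRegions)
  }
  out <- data.frame(
    criterion = c("Number of detections",
                  "Percentage of incorrectly detected from backgrounds",
                  "Average number of undetectable cell nuclear regions per cell nucleus",
                  "Average number of regions detected for each cell nucleus"),
    a = fmtCol(resultA), b = fmtCol(resultB))
  names(out)[2:3] <- names
  attr(out, "numeric") <- data.frame(criterion = out$criterion,
                                     a = numCol(resultA), b = numCol(resultB))
  out
}
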