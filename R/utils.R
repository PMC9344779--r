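# Small shared helpers: seeded evaluation, half-up rounding, colour-space
# conversion on whole images, box arithmetic. Boxes are 0-based, half-open
# (row0, col0, row1, col1) throughout the package.

#' Round half away from zero
#'
#' Decimal rounding in which a trailing 5 always rounds up (for positive
#' values), matching how printed report tables are conventionally rounded.
#' Base `round()` rounds half to even, which would disagree on values such
#' as 0.303125 at four decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' roundHalfUp(0.303125, 4)  # 0.3031
#' roundHalfUp(1 / 37, 3)    # 0.027
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage sub-seed from a global seed. Keeps values inside
# the 32-bit integer range R requires of set.seed().
deriveSeed <- function(globalSeed, stage) {
  offsets <- c(
    scenes = 101L, windows = 211L, split = 307L, grid = 401L,
    eval = 503L, detector = 601L, debris = 701L, misc = 809L
  )
  off <- unname(offsets[stage])
  if (is.na(off)) stop("unknown seeding stage: ", stage)
  as.integer((as.double(globalSeed) * 7919 + off * 104729) %% 2147483647)
}

#' Convert an RGB image array to HSV planes
#'
#' @param image numeric array `H x W x 3` with values in `[0, 1]`.
#' @return list with matrices `h`, `s`, `v`, each `H x W`; hue is in
#'   `[0, 1]` (0 = red, 1/3 = green, 2/3 = blue).
#' @export
rgbToHsv <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  d <- dim(image)[1:2]
  m <- matrix(aperm(image, c(3L, 1L, 2L)), nrow = 3L)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(
    h = matrix(hsv[1L, ], d[1], d[2]),
    s = matrix(hsv[2L, ], d[1], d[2]),
    v = matrix(hsv[3L, ], d[1], d[2])
  )
}

# Single HSV triple -> RGB triple in [0,1].
hsv1 <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

# Is hue h inside a band? Bands may wrap around 1 (e.g. red/orange
# [0.9, 1] + [0, 0.12] passed as c(0.9, 0.12)).
hueInBand <- function(h, band) {
  if (band[1] <= band[2]) h >= band[1] & h <= band[2] else h >= band[1] | h <= band[2]
}

# ---- box helpers (0-based, half-open) --------------------------------------

boxIntersect <- function(a, b) {
  r0 <- max(a[1], b[1]); c0 <- max(a[2], b[2])
  r1 <- min(a[3], b[3]); c1 <- min(a[4], b[4])
  if (r1 <= r0 || c1 <= c0) return(NULL)
  c(r0, c0, r1, c1)
}

boxArea <- function(b) max(0, b[3] - b[1]) * max(0, b[4] - b[2])

# Subset of a cropped mask (logical matrix living at `box`) covered by
# `clip` (another 0-based half-open box). Returns number of TRUE pixels.
maskAreaInBox <- function(mask, box, clip) {
  it <- boxIntersect(box, clip)
  if (is.null(it)) return(0L)
  rows <- (it[1] - box[1] + 1L):(it[3] - box[1])
  cols <- (it[2] - box[2] + 1L):(it[4] - box[2])
  sum(mask[rows, cols])
}

# Overlap (pixel count) between two cropped masks at their boxes.
maskOverlap <- function(maskA, boxA, maskB, boxB) {
  it <- boxIntersect(boxA, boxB)
  if (is.null(it)) return(0L)
  ra <- (it[1] - boxA[1] + 1L):(it[3] - boxA[1])
  ca <- (it[2] - boxA[2] + 1L):(it[4] - boxA[2])
  rb <- (it[1] - boxB[1] + 1L):(it[3] - boxB[1])
  cb <- (it[2] - boxB[2] + 1L):(it[4] - boxB[2])
  sum(maskA[ra, ca] & maskB[rb, cb])
}

# Embed a cropped mask into a full-size logical raster.
embedMask <- function(mask, box, imageSize) {
  out <- matrix(FALSE, imageSize[1], imageSize[2])
  out[(box[1] + 1L):box[3], (box[2] + 1L):box[4]] <- mask
  out
}

# Clip numeric array into [0, 1].
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
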