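# Synthetic Papanicolaou-like cytology fields with exact per-instance ground
# truth. Scenes emulate liquid-based preparations: sparse non-overlapping
# cells on a pale background, each an elliptical nucleus inside a paler
# concentric cytoplasm halo, plus small grey/green debris blobs. Basal
# (blue) lineage nuclei have hue in [0.55, 0.72]; superficial (red/orange)
# lineage near 0. Colours are synthesized in HSV and converted to RGB.

#' Create a synthetic scene configuration
#'
#' Defaults describe the study conditions: `1024 x 1280` fields (the size
#' the source images are saved at), non-overlapping cells as in
#' liquid-based cytology, and stain bands that make "blue-stained" a
#' testable hue predicate.
#'
#' @param nBlue,nRed number of blue- (basal) and red-lineage (superficial)
#'   cells to place.
#' @param imageSize integer `(H, W)` pixels.
#' @param nucleusRadiusRange uniform sampling range (px) of each nucleus
#'   semi-axis.
#' @param ncRatioRange nucleus-to-cytoplasm area ratio range in `(0, 1]`.
#' @param debrisDensity expected debris blobs per megapixel.
#' @param overlapFraction 0 keeps cell footprints disjoint; values toward 1
#'   progressively relax the placement separation (stress mode; untested
#'   territory for real specimens).
#' @param stainNoiseSd sd of Gaussian RGB noise (intensity units on
#'   `[0, 1]`).
#' @param seed RNG seed; scenes are a pure function of (config, seed).
#' @return a [SceneConfig-class] object.
#' @export
#' @examples
#' cfg <- sceneConfig(nBlue = 5, nRed = 3, imageSize = c(288, 384), seed = 7)
#' scene <- generateScene(cfg)
#' length(sceneInstances(scene))
sceneConfig <- function(nBlue = 12L, nRed = 8L, imageSize = c(1024L, 1280L),
                        nucleusRadiusRange = c(9, 16), ncRatioRange = c(0.25, 0.6),
                        debrisDensity = 15, overlapFraction = 0,
                        stainNoiseSd = 0.015, seed = 1L) {
  new("SceneConfig",
      nBlue = as.integer(nBlue), nRed = as.integer(nRed),
      imageSize = as.integer(imageSize),
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      ncRatioRange = as.numeric(ncRatioRange),
      debrisDensity = as.numeric(debrisDensity),
      overlapFraction = as.numeric(overlapFraction),
      stainNoiseSd = as.numeric(stainNoiseSd), seed = as.integer(seed))
}

# Stain palette: hue/saturation/value sampling ranges per lineage and for
# background, cytoplasm and debris. Package-level constants, not knobs.
.stain <- list(
  blueHue = c(0.58, 0.68), redHue = c(0.02, 0.10),
  blueBand = c(0.55, 0.72), redBand = c(0.90, 0.12),   # acceptance bands (red wraps)
  nucleusSat = c(0.55, 0.85), nucleusVal = c(0.35, 0.55),
  cytoSat = c(0.08, 0.18), cytoVal = c(0.78, 0.88),
  debrisHue = c(0.22, 0.40), debrisSat = c(0.05, 0.20), debrisVal = c(0.45, 0.75),
  background = c(h = 0.60, s = 0.02, v = 0.94)
)

#' Hue bands used for the blue / red lineages
#'
#' @return list with `blue` (interval) and `red` (wrapping interval,
#'   `c(lo, hi)` meaning `[lo, 1] + [0, hi]`).
#' @export
stainHueBands <- function() list(blue = .stain$blueBand, red = .stain$redBand)

# Rasterize a rotated ellipse. Returns NULL if empty, else
# list(box = 0-based half-open int4, mask = logical matrix).
rasterEllipse <- function(center, a, b, rot, H, W) {
  rmax <- max(a, b)
  r0 <- max(0L, as.integer(floor(center[1] - rmax)))
  c0 <- max(0L, as.integer(floor(center[2] - rmax)))
  r1 <- min(H, as.integer(ceiling(center[1] + rmax)) + 1L)
  c1 <- min(W, as.integer(ceiling(center[2] + rmax)) + 1L)
  if (r1 <= r0 || c1 <= c0) return(NULL)
  dx <- (r0:(r1 - 1L)) - center[1]
  dy <- (c0:(c1 - 1L)) - center[2]
  cs <- cos(rot); sn <- sin(rot)
  U <- outer(dx * cs, dy * sn, "+")
  V <- outer(-dx * sn, dy * cs, "+")
  mask <- (U / a)^2 + (V / b)^2 <= 1
  if (!any(mask)) return(NULL)
  list(box = c(r0, c0, r1, c1), mask = mask)
}

# Linear indices (channel 1) of a cropped mask's TRUE pixels inside an
# H x W image; painting uses these at the call site so the image array is
# modified in place (a helper taking the array would force a full copy per
# region).
regionIndices <- function(box, mask, H) {
  px <- which(mask, arr.ind = TRUE)
  (px[, 1] + box[1]) + (px[, 2] + box[2] - 1L) * H
}

#' Construct a nucleus instance directly
#'
#' Low-level constructor, mainly for composing hand-built scenes in tests
#' and examples; [generateScene()] builds instances itself.
#'
#' @param id integer instance id (>= 1).
#' @param lineage `"blue"` or `"red"`.
#' @param mask full-image logical matrix or cropped mask (with `box`).
#' @param box 0-based half-open bounding box when `mask` is cropped;
#'   derived from the mask extent when omitted.
#' @param center,semiAxes,rotation geometry metadata; derived from the mask
#'   centroid when omitted.
#' @return a [NucleusInstance-class].
#' @export
nucleusInstance <- function(id, lineage, mask, box = NULL,
                            center = NULL, semiAxes = NULL, rotation = 0) {
  if (is.null(box)) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("mask is empty")
    r <- range(idx[, 1]); c <- range(idx[, 2])
    box <- c(r[1] - 1L, c[1] - 1L, r[2], c[2])
    mask <- mask[r[1]:r[2], c[1]:c[2], drop = FALSE]
  }
  if (is.null(center)) {
    idx <- which(mask, arr.ind = TRUE)
    center <- c(mean(idx[, 1]) - 1 + box[1], mean(idx[, 2]) - 1 + box[2])
  }
  if (is.null(semiAxes)) semiAxes <- c(nrow(mask), ncol(mask)) / 2
  new("NucleusInstance", id = as.integer(id), lineage = lineage,
      center = as.numeric(center), semiAxes = as.numeric(semiAxes),
      rotation = as.numeric(rotation), box = as.integer(box),
      mask = mask)
}

#' Construct a scene from an image and instances
#'
#' Low-level constructor for hand-built fixtures; see [generateScene()] for
#' the generator.
#'
#' @param image RGB array `H x W x 3`.
#' @param instances list of [NucleusInstance-class].
#' @param id scene identifier.
#' @param config optional [SceneConfig-class]; a matching-size default is
#'   recorded when omitted.
#' @param debrisCount,seed metadata.
#' @return a [SyntheticScene-class].
#' @export
syntheticScene <- function(image, instances = list(), id = "scene",
                           config = NULL, debrisCount = 0L, seed = 0L) {
  if (is.null(config)) {
    config <- sceneConfig(nBlue = 0L, nRed = 0L, imageSize = dim(image)[1:2],
                          seed = as.integer(seed))
  }
  new("SyntheticScene", image = image, instances = instances,
      debrisCount = as.integer(debrisCount), seed = as.integer(seed),
      config = config, id = id)
}

#' Generate a synthetic cytology scene
#'
#' Places `nBlue + nRed` cells by rejection sampling (cytoplasm footprints
#' kept apart according to `overlapFraction`), draws cytoplasm halos, then
#' nuclei, then debris, and finally adds Gaussian stain noise. Regenerating
#' with an identical config reproduces the image bit-exactly.
#'
#' @param config a [SceneConfig-class].
#' @param id scene identifier; defaults to `"scene-<seed>"`.
#' @return a [SyntheticScene-class] with exactly `nBlue` blue- and `nRed`
#'   red-lineage instances.
#' @section Errors: when cells cannot be placed without violating the
#'   separation constraint after bounded retries, a capacity error of class
#'   `cytodetectCapacityError` is signalled.
#' @export
generateScene <- function(config, id = sprintf("scene-%d", config@seed)) {
  validObject(config)
  H <- config@imageSize[1]; W <- config@imageSize[2]
  withSeed(config@seed, {
    bg <- .stain$background
    bgCol <- hsv1(bg["h"], bg["s"], bg["v"])
    img <- array(rep(bgCol, each = H * W), dim = c(H, W, 3))

    nCells <- config@nBlue + config@nRed
    lineage <- rep(c("blue", "red"), c(config@nBlue, config@nRed))
    cells <- vector("list", nCells)
    placedCenter <- matrix(NA_real_, nCells, 2)
    placedReach <- numeric(nCells)
    sep <- 1 - config@overlapFraction
    for (k in seq_len(nCells)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        ax <- stats::runif(2, config@nucleusRadiusRange[1], config@nucleusRadiusRange[2])
        rot <- stats::runif(1, 0, pi)
        nc <- stats::runif(1, config@ncRatioRange[1], config@ncRatioRange[2])
        cytoScale <- 1 / sqrt(nc)
        reach <- max(ax) * cytoScale
        if (H - 2 * (reach + 2) <= 1 || W - 2 * (reach + 2) <= 1) next
        ctr <- c(stats::runif(1, reach + 2, H - 1 - reach - 2),
                 stats::runif(1, reach + 2, W - 1 - reach - 2))
        ok <- TRUE
        if (k > 1L) {
          prev <- seq_len(k - 1L)
          dist <- sqrt((placedCenter[prev, 1] - ctr[1])^2 +
                       (placedCenter[prev, 2] - ctr[2])^2)
          ok <- all(dist >= (placedReach[prev] + reach + 2) * sep)
        }
        if (!ok) next
        hue <- if (lineage[k] == "blue") {
          stats::runif(1, .stain$blueHue[1], .stain$blueHue[2])
        } else {
          stats::runif(1, .stain$redHue[1], .stain$redHue[2])
        }
        cells[[k]] <- list(
          center = ctr, semiAxes = ax, rotation = rot, cytoScale = cytoScale,
          hue = hue,
          nucleusCol = hsv1(hue, stats::runif(1, .stain$nucleusSat[1], .stain$nucleusSat[2]),
                            stats::runif(1, .stain$nucleusVal[1], .stain$nucleusVal[2])),
          cytoCol = hsv1(hue + stats::runif(1, -0.02, 0.02),
                         stats::runif(1, .stain$cytoSat[1], .stain$cytoSat[2]),
                         stats::runif(1, .stain$cytoVal[1], .stain$cytoVal[2]))
        )
        placedCenter[k, ] <- ctr
        placedReach[k] <- reach
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(errorCondition(
          sprintf(paste0("could not place cell %d of %d after 200 attempts; ",
                         "reduce cell counts, overlap separation or cell size"),
                  k, nCells),
          class = "cytodetectCapacityError"))
      }
    }

    # cytoplasm halos first, then nuclei on top
    HW <- H * W
    for (cell in cells) {
      cy <- rasterEllipse(cell$center, cell$semiAxes[1] * cell$cytoScale,
                          cell$semiAxes[2] * cell$cytoScale, cell$rotation, H, W)
      ri <- regionIndices(cy$box, cy$mask, H)
      img[ri] <- cell$cytoCol[1]
      img[ri + HW] <- cell$cytoCol[2]
      img[ri + 2L * HW] <- cell$cytoCol[3]
    }
    instances <- vector("list", nCells)
    for (k in seq_len(nCells)) {
      cell <- cells[[k]]
      nu <- rasterEllipse(cell$center, cell$semiAxes[1], cell$semiAxes[2],
                          cell$rotation, H, W)
      ri <- regionIndices(nu$box, nu$mask, H)
      img[ri] <- cell$nucleusCol[1]
      img[ri + HW] <- cell$nucleusCol[2]
      img[ri + 2L * HW] <- cell$nucleusCol[3]
      instances[[k]] <- new("NucleusInstance", id = k, lineage = lineage[k],
                            center = cell$center, semiAxes = cell$semiAxes,
                            rotation = cell$rotation, box = as.integer(nu$box),
                            mask = nu$mask)
    }

    nDebris <- stats::rpois(1, config@debrisDensity * H * W / 1e6)
    drawn <- 0L
    if (nDebris > 0L) {
      for (d in seq_len(nDebris)) {
        for (attempt in seq_len(50L)) {
          ctr <- c(stats::runif(1, 2, H - 3), stats::runif(1, 2, W - 3))
          nearNucleus <- any(vapply(instances, function(inst) {
            ctr[1] >= inst@box[1] - 3 && ctr[1] <= inst@box[3] + 3 &&
              ctr[2] >= inst@box[2] - 3 && ctr[2] <= inst@box[4] + 3
          }, logical(1)))
          if (nearNucleus) next
          bl <- rasterEllipse(ctr, stats::runif(1, 1.5, 4.5), stats::runif(1, 1.5, 4.5),
                              stats::runif(1, 0, pi), H, W)
          if (is.null(bl)) next
          col <- hsv1(stats::runif(1, .stain$debrisHue[1], .stain$debrisHue[2]),
                      stats::runif(1, .stain$debrisSat[1], .stain$debrisSat[2]),
                      stats::runif(1, .stain$debrisVal[1], .stain$debrisVal[2]))
          ri <- regionIndices(bl$box, bl$mask, H)
          img[ri] <- col[1]
          img[ri + HW] <- col[2]
          img[ri + 2L * HW] <- col[3]
          drawn <- drawn + 1L
          break
        }
      }
    }

    if (config@stainNoiseSd > 0) {
      img <- clip01(img + stats::rnorm(length(img), 0, config@stainNoiseSd))
    }

    new("SyntheticScene", image = img, instances = instances,
        debrisCount = drawn, seed = config@seed, config = config, id = id)
  })
}

# ---- accessors -------------------------------------------------------------

#' Scene image
#' @param x a [SyntheticScene-class].
#' @return numeric `H x W x 3` array.
#' @rdname sceneImage
#' @export
setMethod("sceneImage", "SyntheticScene", function(x) x@image)

#' Scene instances
#' @param x a [SyntheticScene-class].
#' @return list of [NucleusInstance-class].
#' @rdname sceneInstances
#' @export
setMethod("sceneInstances", "SyntheticScene", function(x) x@instances)

#' Instance lineages
#' @param x a [SyntheticScene-class].
#' @return character vector of `"blue"` / `"red"`, one per instance.
#' @rdname lineages
#' @export
setMethod("lineages", "SyntheticScene", function(x)
  vapply(x@instances, function(i) i@lineage, character(1)))

#' Binary mask of one instance
#' @param x a [SyntheticScene-class].
#' @param id instance id.
#' @param full return a full image-sized raster (`TRUE`) or the cropped
#'   mask with its box as attributes (`FALSE`).
#' @return logical matrix.
#' @rdname instanceMask
#' @export
setMethod("instanceMask", "SyntheticScene", function(x, id, full = TRUE) {
  inst <- NULL
  for (i in x@instances) if (i@id == id) { inst <- i; break }
  if (is.null(inst)) stop("no instance with id ", id)
  if (full) return(embedMask(inst@mask, inst@box, dim(x@image)[1:2]))
  structure(inst@mask, box = inst@box)
})

#' Combined labelled mask
#'
#' Integer matrix, 0 for background and the instance id elsewhere. When
#' masks overlap (stress mode) later ids win.
#'
#' @param x a [SyntheticScene-class].
#' @return integer matrix `H x W`.
#' @rdname labelMask
#' @export
setMethod("labelMask", "SyntheticScene", function(x) {
  d <- dim(x@image)
  lab <- matrix(0L, d[1], d[2])
  for (inst in x@instances) {
    rows <- (inst@box[1] + 1L):inst@box[3]
    cols <- (inst@box[2] + 1L):inst@box[4]
    sub <- lab[rows, cols]
    sub[inst@mask] <- inst@id
    lab[rows, cols] <- sub
  }
  lab
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  lin <- lineages(object)
  cat(sprintf("SyntheticScene '%s': %d x %d px, %d instances (%d blue, %d red), %d debris, seed %d\n",
              object@id, d[1], d[2], length(object@instances),
              sum(lin == "blue"), sum(lin == "red"),
              object@debrisCount, object@seed))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0("SceneConfig: %d blue + %d red cells on %d x %d px, ",
                     "nucleus semi-axes [%g, %g] px, N/C [%g, %g], debris %g/Mpx, ",
                     "overlap %g, noise sd %g, seed %d\n"),
              object@nBlue, object@nRed, object@imageSize[1], object@imageSize[2],
              object@nucleusRadiusRange[1], object@nucleusRadiusRange[2],
              object@ncRatioRange[1], object@ncRatioRange[2],
              object@debrisDensity, object@overlapFraction,
              object@stainNoiseSd, object@seed))
})

# ---- export ----------------------------------------------------------------

# Polygon approximation of a rotated ellipse, COCO (x, y) order.
ellipsePolygon <- function(center, a, b, rot, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- a * cos(t); v <- b * sin(t)
  row <- center[1] + u * cos(rot) - v * sin(rot)
  col <- center[2] + u * sin(rot) + v * cos(rot)
  as.numeric(rbind(col, row))  # interleaved x1, y1, x2, y2, ...
}

#' Export a scene with its ground truth
#'
#' Writes the image (TIFF and PNG), one 8-bit 0/255 mask PNG per instance,
#' a combined labelled mask (16-bit TIFF, plus an 8-bit PNG when ids fit),
#' a COCO-style annotation JSON (boxes, ellipse polygons, lineage as
#' category) and a CSV manifest listing every artifact.
#'
#' @param scene a [SyntheticScene-class].
#' @param directory output directory (created if missing).
#' @return (invisibly) the manifest data.frame (`kind`, `path`).
#' @export
exportGroundTruth <- function(scene, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  pathOf <- function(...) file.path(directory, paste0(scene@id, "_", ...))
  manifest <- list()
  add <- function(kind, path) manifest[[length(manifest) + 1L]] <<- data.frame(kind = kind, path = path)

  tryCatch({
    tiffPath <- pathOf("image.tiff")
    tiff::writeTIFF(scene@image, tiffPath, bits.per.sample = 8L)
    add("image_tiff", tiffPath)
    pngPath <- pathOf("image.png")
    png::writePNG(scene@image, pngPath)
    add("image_png", pngPath)

    d <- dim(scene@image)
    for (inst in scene@instances) {
      mp <- pathOf(sprintf("mask_%03d.png", inst@id))
      png::writePNG(embedMask(inst@mask, inst@box, d[1:2]) * 1, mp)
      add(sprintf("instance_mask_%d", inst@id), mp)
    }

    lab <- labelMask(scene)
    labTiff <- pathOf("labels.tiff")
    tiff::writeTIFF(lab / 65535, labTiff, bits.per.sample = 16L)
    add("label_mask_tiff16", labTiff)
    if (length(scene@instances) == 0L || max(lab) <= 255L) {
      labPng <- pathOf("labels.png")
      png::writePNG(lab / 255, labPng)
      add("label_mask_png8", labPng)
    }

    anns <- lapply(scene@instances, function(inst) {
      list(id = inst@id, image_id = 1L,
           category_id = if (inst@lineage == "blue") 1L else 2L,
           bbox = c(inst@box[2], inst@box[1],
                    inst@box[4] - inst@box[2], inst@box[3] - inst@box[1]),
           area = sum(inst@mask),
           segmentation = list(ellipsePolygon(inst@center, inst@semiAxes[1],
                                              inst@semiAxes[2], inst@rotation)),
           iscrowd = 0L)
    })
    coco <- list(
      images = list(list(id = 1L, file_name = basename(pngPath),
                         height = d[1], width = d[2])),
      categories = list(list(id = 1L, name = "nucleus_blue"),
                        list(id = 2L, name = "nucleus_red")),
      annotations = anns
    )
    jsonPath <- pathOf("annotations.json")
    jsonlite::write_json(coco, jsonPath, auto_unbox = TRUE, digits = NA)
    add("annotations_json", jsonPath)
  }, error = function(e) {
    stop(sprintf("ground-truth export to '%s' failed: %s", directory, conditionMessage(e)))
  })

  man <- do.call(rbind, manifest)
  manPath <- pathOf("manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  invisible(man)
}
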