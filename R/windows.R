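# Sliding-window dataset construction: 96x96 tiling on a non-overlapping
# grid, the "more than half of the nucleus" positive-label rule restricted
# to blue-lineage nuclei, balanced assembly, and the stratified 3:1 split.

#' Tile an image into fixed-size windows
#'
#' Windows have their top-left corners at `(i * stride, j * stride)`
#' (0-based) and must lie fully inside the image; partial edge windows are
#' dropped, so a `1024 x 1280` image yields `10 x 13 = 130` windows at the
#' default `window = stride = 96`.
#'
#' @param image numeric `H x W x 3` array (or `H x W` matrix).
#' @param window window side in pixels.
#' @param stride step between window origins; defaults to `window`
#'   (non-overlapping grid).
#' @return list with `origins` (n x 2 integer matrix of 0-based
#'   `(row0, col0)`) and `patches` (`window x window x 3 x n` array, or
#'   `NULL` when `extract = FALSE`).
#' @param extract set `FALSE` to compute origins only.
#' @export
tileImage <- function(image, window = 96L, stride = window, extract = TRUE) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (window > min(H, W))
    stop(sprintf("window (%d) larger than image (%d x %d)", window, H, W))
  rows <- seq.int(0L, H - window, by = stride)
  cols <- seq.int(0L, W - window, by = stride)
  origins <- cbind(row0 = rep(rows, times = length(cols)),
                   col0 = rep(cols, each = length(rows)))
  patches <- NULL
  if (extract) {
    if (length(d) == 2L) dim(image) <- c(d, 1L)
    nC <- dim(image)[3]
    patches <- array(0, dim = c(window, window, nC, nrow(origins)))
    for (i in seq_len(nrow(origins))) {
      r <- origins[i, 1]; c <- origins[i, 2]
      patches[, , , i] <- image[(r + 1L):(r + window), (c + 1L):(c + window), ]
    }
  }
  list(origins = origins, patches = patches)
}

#' Label one window against scene ground truth
#'
#' A window is labelled `"nucleus"` iff some blue-lineage instance has
#' strictly more than `coverageThreshold` of its total mask area inside the
#' window. Red-lineage instances never produce a positive label. The
#' coverage fraction is per nucleus (mask area inside window / total mask
#' area), not a window-area fraction.
#'
#' @param origin 0-based `(row0, col0)` of the window's top-left corner.
#' @param scene a [SyntheticScene-class].
#' @param coverageThreshold strict lower bound on the covered fraction
#'   (default 0.5, i.e. "more than half").
#' @param window window side in pixels.
#' @return list with `label` (`"nucleus"` / `"non_nucleus"`) and
#'   `coveredIds` (integer ids of all qualifying blue instances).
#' @export
labelWindow <- function(origin, scene, coverageThreshold = 0.5, window = 96L) {
  d <- dim(scene@image)
  win <- c(origin[1], origin[2], origin[1] + window, origin[2] + window)
  if (win[1] < 0L || win[2] < 0L || win[3] > d[1] || win[4] > d[2])
    stop("window must lie fully inside the scene image")
  ids <- integer()
  for (inst in scene@instances) {
    if (inst@lineage != "blue") next
    inside <- maskAreaInBox(inst@mask, inst@box, win)
    if (inside / sum(inst@mask) > coverageThreshold) ids <- c(ids, inst@id)
  }
  list(label = if (length(ids)) "nucleus" else "non_nucleus", coveredIds = ids)
}

# Build a WindowSet from parallel vectors/lists.
newWindowSet <- function(patches, sourceId, row0, col0, label, coveredIds,
                         window = 96L) {
  info <- data.frame(sourceId = sourceId, row0 = row0, col0 = col0,
                     label = label, stringsAsFactors = FALSE)
  info$coveredIds <- coveredIds
  new("WindowSet", patches = patches, info = info, window = as.integer(window))
}

emptyWindowSet <- function(window = 96L) {
  newWindowSet(array(0, dim = c(window, window, 3, 0)),
               character(), integer(), integer(), character(), list(),
               window = window)
}

#' Number of windows in a set
#' @param x a [WindowSet-class].
#' @export
setMethod("length", "WindowSet", function(x) nrow(x@info))

#' Window metadata
#' @param x a [WindowSet-class] or [WindowDataset-class].
#' @return data.frame of per-window metadata (plus a `split` column for
#'   datasets).
#' @rdname windowInfo
#' @export
setMethod("windowInfo", "WindowSet", function(x) x@info)

#' @rdname windowInfo
#' @export
setMethod("windowInfo", "WindowDataset", function(x) {
  rbind(cbind(x@train@info, split = rep("train", nrow(x@train@info))),
        cbind(x@test@info, split = rep("test", nrow(x@test@info))))
})

#' One window sample
#' @param x a [WindowSet-class].
#' @param i sample index.
#' @return list with `patch`, `label`, `origin`, `sourceId`, `coveredIds`.
#' @rdname windowPatch
#' @export
setMethod("windowPatch", "WindowSet", function(x, i) {
  list(patch = x@patches[, , , i],
       label = x@info$label[i],
       origin = c(x@info$row0[i], x@info$col0[i]),
       sourceId = x@info$sourceId[i],
       coveredIds = x@info$coveredIds[[i]])
})

setMethod("show", "WindowSet", function(object) {
  tab <- table(factor(object@info$label, levels = c("nucleus", "non_nucleus")))
  cat(sprintf("WindowSet: %d windows of %d x %d px (%d nucleus, %d non_nucleus)\n",
              length(object), object@window, object@window,
              tab[["nucleus"]], tab[["non_nucleus"]]))
})

#' Train / test subsets and class counts
#' @param x a [WindowDataset-class].
#' @rdname trainSet
#' @export
setMethod("trainSet", "WindowDataset", function(x) x@train)

#' @rdname testSet
#' @export
setMethod("testSet", "WindowDataset", function(x) x@test)

#' @rdname classCounts
#' @export
setMethod("classCounts", "WindowDataset", function(x) x@classCounts)

setMethod("show", "WindowDataset", function(object) {
  cc <- object@classCounts
  cat(sprintf("WindowDataset: %d train / %d test windows (seed %d)\n",
              length(object@train), length(object@test), object@splitSeed))
  print(cc)
})

# Subset a WindowSet by index.
subsetWindowSet <- function(ws, idx) {
  info <- ws@info[idx, , drop = FALSE]
  rownames(info) <- NULL
  new("WindowSet", patches = ws@patches[, , , idx, drop = FALSE],
      info = info, window = ws@window)
}

#' Assemble a balanced window dataset from scenes
#'
#' Tiles every scene on a non-overlapping grid, labels each window with
#' [labelWindow()], and draws exactly `nPerClass` windows of each label
#' without replacement, reproducibly under `seed`.
#'
#' Elements of `scenes` may be [SyntheticScene-class] objects or
#' [SceneConfig-class] objects; configs are generated on the fly (twice:
#' once to enumerate candidate labels, once to extract only the sampled
#' patches), which keeps memory flat for large corpora at the cost of
#' regenerating — generation is deterministic so both passes agree.
#'
#' @param scenes list of scenes and/or scene configs.
#' @param nPerClass windows to draw per label.
#' @param seed sampling seed.
#' @param window,stride tiling geometry.
#' @param coverageThreshold labelling rule threshold.
#' @return a [WindowSet-class] with `2 * nPerClass` samples.
#' @export
assembleBalancedDataset <- function(scenes, nPerClass, seed = 1L,
                                    window = 96L, stride = window,
                                    coverageThreshold = 0.5) {
  nPerClass <- as.integer(nPerClass)
  if (nPerClass < 0L) stop("nPerClass must be >= 0")
  if (nPerClass == 0L) return(emptyWindowSet(window))

  getScene <- function(s, k) {
    if (is(s, "SyntheticScene")) s
    else if (is(s, "SceneConfig")) generateScene(s)
    else stop("scenes must contain SyntheticScene or SceneConfig objects")
  }

  # pass 1: candidate window metadata only
  cand <- vector("list", length(scenes))
  for (k in seq_along(scenes)) {
    scene <- getScene(scenes[[k]], k)
    tl <- tileImage(scene@image, window = window, stride = stride, extract = FALSE)
    n <- nrow(tl$origins)
    labels <- character(n); covered <- vector("list", n)
    for (i in seq_len(n)) {
      lw <- labelWindow(tl$origins[i, ], scene, coverageThreshold, window)
      labels[i] <- lw$label
      covered[[i]] <- lw$coveredIds
    }
    cand[[k]] <- list(sceneIndex = k, sourceId = scene@id,
                      origins = tl$origins, labels = labels, covered = covered)
  }
  allLabels <- unlist(lapply(cand, `[[`, "labels"))
  for (lab in c("nucleus", "non_nucleus")) {
    have <- sum(allLabels == lab)
    if (have < nPerClass)
      stop(sprintf("insufficient '%s' windows: need %d, found %d across %d scene(s)",
                   lab, nPerClass, have, length(scenes)))
  }

  sceneIdx <- rep(seq_along(cand), vapply(cand, function(x) length(x$labels), 1L))
  flatRow <- unlist(lapply(cand, function(x) x$origins[, 1]))
  flatCol <- unlist(lapply(cand, function(x) x$origins[, 2]))
  pick <- withSeed(seed, {
    pos <- sample(which(allLabels == "nucleus"), nPerClass)
    neg <- sample(which(allLabels == "non_nucleus"), nPerClass)
    sort(c(pos, neg))
  })

  # pass 2: extract only the sampled patches, scene by scene
  patches <- array(0, dim = c(window, window, 3, length(pick)))
  srcIds <- character(length(pick)); row0 <- integer(length(pick))
  col0 <- integer(length(pick)); labs <- character(length(pick))
  covIds <- vector("list", length(pick))
  done <- 0L
  for (k in seq_along(scenes)) {
    sel <- pick[sceneIdx[pick] == k]
    if (!length(sel)) next
    scene <- getScene(scenes[[k]], k)
    offset <- if (k == 1L) 0L else sum(vapply(cand[seq_len(k - 1L)],
                                              function(x) length(x$labels), 1L))
    for (p in sel) {
      done <- done + 1L
      local_i <- p - offset
      r <- flatRow[p]; c <- flatCol[p]
      patches[, , , done] <- scene@image[(r + 1L):(r + window), (c + 1L):(c + window), ]
      srcIds[done] <- cand[[k]]$sourceId
      row0[done] <- r; col0[done] <- c
      labs[done] <- cand[[k]]$labels[local_i]
      covIds[[done]] <- cand[[k]]$covered[[local_i]]
    }
  }
  newWindowSet(patches, srcIds, row0, col0, labs, covIds, window = window)
}

#' Stratified train/test split of window samples
#'
#' Per label, allocates train slots by largest-remainder apportionment of
#' `trainFraction * n_total` (per-label floors first, remaining slots to
#' the labels with the largest fractional remainders, ties broken by label
#' name), then samples the allocated windows without replacement under
#' `seed`. A balanced set of 788 windows at `trainFraction = 0.75` yields
#' exactly 591 training and 197 test samples.
#'
#' @param samples a [WindowSet-class].
#' @param trainFraction fraction of samples assigned to training,
#'   in `(0, 1)`.
#' @param seed split seed.
#' @return a [WindowDataset-class].
#' @export
splitDataset <- function(samples, trainFraction = 0.75, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  labels <- samples@info$label
  labNames <- sort(unique(labels))
  nPer <- vapply(labNames, function(l) sum(labels == l), 1L)
  if (any(nPer < 2L))
    stop("each label needs at least 2 samples to split; got: ",
         paste(sprintf("%s=%d", labNames, nPer), collapse = ", "))
  totalTrain <- floor(trainFraction * length(labels))
  base <- floor(trainFraction * nPer)
  remainder <- trainFraction * nPer - base
  extra <- totalTrain - sum(base)
  alloc <- base
  if (extra > 0L) {
    ord <- order(-remainder, labNames)
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
  }
  trainIdx <- withSeed(seed, {
    unlist(lapply(seq_along(labNames), function(j) {
      idx <- which(labels == labNames[j])
      sample(idx, alloc[j])
    }))
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(labels), trainIdx)
  train <- subsetWindowSet(samples, trainIdx)
  test <- subsetWindowSet(samples, testIdx)
  cc <- rbind(train = vapply(labNames, function(l) sum(train@info$label == l), 1L),
              test = vapply(labNames, function(l) sum(test@info$label == l), 1L))
  colnames(cc) <- labNames
  new("WindowDataset", train = train, test = test,
      splitSeed = as.integer(seed), classCounts = cc)
}

#' Export window patches and a dataset index
#'
#' Writes each patch as `{source}_{row}_{col}_{label}.png` and an index CSV
#' (`sourceId`, `row0`, `col0`, `label`, `split`).
#'
#' @param dataset a [WindowDataset-class].
#' @param directory output directory.
#' @param writePatches write the individual patch PNGs (default `TRUE`);
#'   the index CSV is always written.
#' @return (invisibly) the path of the index CSV.
#' @export
exportWindowDataset <- function(dataset, directory, writePatches = TRUE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  info <- windowInfo(dataset)
  if (writePatches) {
    sets <- list(train = dataset@train, test = dataset@test)
    for (ws in sets) {
      for (i in seq_len(length(ws))) {
        nm <- sprintf("%s_%d_%d_%s.png", ws@info$sourceId[i],
                      ws@info$row0[i], ws@info$col0[i], ws@info$label[i])
        png::writePNG(ws@patches[, , , i], file.path(directory, nm))
      }
    }
  }
  idx <- file.path(directory, "dataset_index.csv")
  utils::write.csv(info[, c("sourceId", "row0", "col0", "label", "split")],
                   idx, row.names = FALSE)
  invisible(idx)
}
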