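# The configurable 96x96 two-class patch classifier, its configuration-grid
# runner, whole-image scoring and the red/yellow probability overlay.
#
# Layer-counting convention: the reported depth counts every convolution,
# activation, pooling, dropout, affine and softmax layer. The two stock
# architectures are built from repeated conv -> activation -> pool blocks
# (with doubled conv -> activation pairs in the deeper one) plus dropout and
# two affine layers:
#   depth 18: [conv act pool] x4, dropout, affine, act, dropout, affine, softmax
#   depth 24: [conv act conv act pool] x3, [conv act pool], dropout, affine,
#             act, dropout, affine, softmax
# Both reduce a 96x96 input to 6x6 feature maps over four pooling stages.
# Filter counts (8 -> 16 -> 32 -> 32) and 3x3 kernels are package defaults;
# they are modest enough for CPU training at desk scale.

#' Supported counted depths
#' @return integer vector of supported `nLayers` values.
#' @export
supportedDepths <- function() c(18L, 24L)

#' Create a patch-classifier configuration
#'
#' One cell of the configuration grid: activation function, epochs, counted
#' depth and dropout rate, plus training hyper-parameters (ADAM step size
#' and minibatch size are package defaults, as is the seed).
#'
#' @param activation `"ReLU"` or `"Sigmoid"`.
#' @param epochs training epochs.
#' @param nLayers counted depth; one of [supportedDepths()].
#' @param dropoutRate dropout probability in `[0, 1)`.
#' @param learningSeed seed for weight initialisation, shuffling and
#'   dropout.
#' @param batchSize minibatch size.
#' @param learningRate ADAM step size.
#' @return a [PatchClassifierConfig-class].
#' @export
patchClassifierConfig <- function(activation = "ReLU", epochs = 20L,
                                  nLayers = 18L, dropoutRate = 0.25,
                                  learningSeed = 1L, batchSize = 32L,
                                  learningRate = 1e-3) {
  activation <- c(relu = "ReLU", sigmoid = "Sigmoid")[[tolower(activation)]]
  new("PatchClassifierConfig", activation = activation,
      epochs = as.integer(epochs), nLayers = as.integer(nLayers),
      dropoutRate = as.numeric(dropoutRate),
      learningSeed = as.integer(learningSeed),
      batchSize = as.integer(batchSize), learningRate = as.numeric(learningRate))
}

#' The default 9-row configuration grid
#'
#' ReLU at epochs 5/20/50 for depths 18 and 24 with dropout 0.25, ReLU at
#' depth 18 with dropout 0.5 (epochs 5 and 20), and a Sigmoid row.
#'
#' @param learningSeed seed applied to every configuration.
#' @param batchSize,learningRate shared training hyper-parameters.
#' @return list of [PatchClassifierConfig-class] objects.
#' @export
defaultConfigGrid <- function(learningSeed = 1L, batchSize = 32L,
                              learningRate = 1e-3) {
  rows <- list(
    list("ReLU", 5L, 18L, 0.25), list("ReLU", 20L, 18L, 0.25),
    list("ReLU", 50L, 18L, 0.25), list("ReLU", 5L, 24L, 0.25),
    list("ReLU", 20L, 24L, 0.25), list("ReLU", 50L, 24L, 0.25),
    list("ReLU", 5L, 18L, 0.5), list("ReLU", 20L, 18L, 0.5),
    list("Sigmoid", 20L, 18L, 0.25)
  )
  lapply(rows, function(r) patchClassifierConfig(r[[1]], r[[2]], r[[3]], r[[4]],
                                                 learningSeed = learningSeed,
                                                 batchSize = batchSize,
                                                 learningRate = learningRate))
}

# Architecture plan for a counted depth: list of layer descriptors.
archPlan <- function(nLayers) {
  if (nLayers == 18L) {
    list(c(3, 8), "act", "pool", c(8, 16), "act", "pool",
         c(16, 32), "act", "pool", c(32, 32), "act", "pool")
  } else if (nLayers == 24L) {
    list(c(3, 8), "act", c(8, 8), "act", "pool",
         c(8, 16), "act", c(16, 16), "act", "pool",
         c(16, 32), "act", c(32, 32), "act", "pool",
         c(32, 32), "act", "pool")
  } else {
    stop("unsupported nLayers ", nLayers, "; supported depths: ",
         paste(supportedDepths(), collapse = ", "))
  }
}

#' Build a patch classifier
#'
#' Instantiates the architecture for `config@nLayers` with seeded weight
#' initialisation (He-scaled normal for ReLU, Xavier for Sigmoid). The
#' network takes `inputSize x inputSize x 3` patches and emits two softmax
#' class probabilities (`nucleus`, `non_nucleus`).
#'
#' @param config a [PatchClassifierConfig-class].
#' @param inputSize input patch side; must be divisible by 16 (four pooling
#'   stages).
#' @return an untrained [PatchClassifier-class].
#' @export
buildPatchClassifier <- function(config, inputSize = 96L) {
  validObject(config)
  inputSize <- as.integer(inputSize)
  if (inputSize %% 16L != 0L) stop("inputSize must be divisible by 16")
  plan <- archPlan(config@nLayers)
  gain <- if (config@activation == "ReLU") 2 else 1
  layers <- withSeed(config@learningSeed, {
    out <- list()
    side <- inputSize
    lastC <- 3L
    for (p in plan) {
      if (is.character(p) && p == "act") {
        out[[length(out) + 1L]] <- list(type = "act")
      } else if (is.character(p) && p == "pool") {
        out[[length(out) + 1L]] <- list(type = "pool")
        side <- side %/% 2L
      } else {
        cin <- p[1]; cout <- p[2]
        out[[length(out) + 1L]] <- list(
          type = "conv",
          W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(gain / (9 * cin))),
                     9 * cin, cout),
          b = numeric(cout), cin = cin, cout = cout)
        lastC <- cout
      }
    }
    flat <- side * side * lastC
    hidden <- 64L
    out[[length(out) + 1L]] <- list(type = "dropout", rate = config@dropoutRate)
    out[[length(out) + 1L]] <- list(
      type = "affine",
      W = matrix(stats::rnorm(hidden * flat, 0, sqrt(gain / flat)), hidden, flat),
      b = numeric(hidden))
    out[[length(out) + 1L]] <- list(type = "act")
    out[[length(out) + 1L]] <- list(type = "dropout", rate = config@dropoutRate)
    out[[length(out) + 1L]] <- list(
      type = "affine",
      W = matrix(stats::rnorm(2L * hidden, 0, sqrt(gain / hidden)), 2L, hidden),
      b = numeric(2L))
    out[[length(out) + 1L]] <- list(type = "softmax")
    out
  })
  stopifnot(length(layers) == config@nLayers)
  new("PatchClassifier", config = config, layers = layers,
      inputSize = inputSize, trained = FALSE)
}

#' Counted depth of a classifier
#' @param classifier a [PatchClassifier-class].
#' @return integer layer count under the package's counting convention.
#' @export
countedDepth <- function(classifier) length(classifier@layers)

setMethod("show", "PatchClassifier", function(object) {
  cfg <- object@config
  cat(sprintf("PatchClassifier: depth %d, %s, dropout %.2f, input %d x %d x 3, %s\n",
              countedDepth(object), cfg@activation, cfg@dropoutRate,
              object@inputSize, object@inputSize,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "PatchClassifierConfig", function(object) {
  cat(sprintf("PatchClassifierConfig: %s, %d epochs, depth %d, dropout %.2f, batch %d, lr %g, seed %d\n",
              object@activation, object@epochs, object@nLayers, object@dropoutRate,
              object@batchSize, object@learningRate, object@learningSeed))
})

# Class order for the two softmax outputs.
.classLevels <- c("nucleus", "non_nucleus")

# WindowSet -> centred input array and class-index vector.
prepareBatch <- function(ws) {
  list(X = ws@patches - 0.5,
       y = match(ws@info$label, .classLevels))
}

#' Class probabilities for a stack of patches
#'
#' @param classifier a [PatchClassifier-class].
#' @param patches `side x side x 3 x n` array with values in `[0, 1]`.
#' @param chunk forward-pass batch size.
#' @return `n x 2` matrix of probabilities, columns `nucleus` and
#'   `non_nucleus`; each row sums to 1.
#' @export
predictPatchProbs <- function(classifier, patches, chunk = 64L) {
  d <- dim(patches)
  stopifnot(length(d) == 4L, d[1] == classifier@inputSize,
            d[2] == classifier@inputSize, d[3] == 3L)
  n <- d[4]
  P <- matrix(NA_real_, n, 2, dimnames = list(NULL, .classLevels))
  X <- patches - 0.5
  at <- 1L
  while (at <= n) {
    hi <- min(at + chunk - 1L, n)
    fw <- nnForward(classifier@layers, X[, , , at:hi, drop = FALSE],
                    classifier@config@activation, training = FALSE)
    P[at:hi, ] <- t(fw$P)
    at <- hi + 1L
  }
  P
}

# Evaluation-mode loss and accuracy over a WindowSet.
evalOnSet <- function(classifier, ws, chunk = 64L) {
  if (length(ws) == 0L) return(list(loss = NA_real_, acc = NA_real_))
  pb <- prepareBatch(ws)
  P <- predictPatchProbs(classifier, ws@patches, chunk = chunk)
  loss <- crossEntropy(t(P), pb$y)
  acc <- mean(max.col(P, ties.method = "first") == pb$y)
  list(loss = loss, acc = acc)
}

#' Train a patch classifier
#'
#' Minimises categorical cross-entropy with ADAM for `config@epochs`
#' passes over the training split (seeded shuffling, minibatches of
#' `config@batchSize`). The per-epoch history records the running
#' training-mode loss/accuracy over that epoch's minibatches plus an
#' evaluation pass over the test split; the final reported metrics are
#' full evaluation passes (dropout off) over both splits. Reproducible:
#' identical seeds give identical histories.
#'
#' @param classifier an untrained (or pre-trained) [PatchClassifier-class].
#' @param dataset a [WindowDataset-class]; both splits must be non-empty.
#' @param verbose print one line per epoch.
#' @return a [TrainResult-class] containing the trained classifier.
#' @export
trainPatchClassifier <- function(classifier, dataset, verbose = FALSE) {
  if (length(dataset@train) == 0L) stop("training split is empty")
  if (length(dataset@test) == 0L) stop("test split is empty")
  cfg <- classifier@config
  tr <- prepareBatch(dataset@train)
  n <- dim(tr$X)[4]
  layers <- classifier@layers
  state <- adamInit(layers)
  hist <- vector("list", cfg@epochs)
  t <- 0L
  withSeed(deriveSeed(cfg@learningSeed, "misc"), {
    for (epoch in seq_len(cfg@epochs)) {
      perm <- sample.int(n)
      at <- 1L
      epLoss <- 0; epCorrect <- 0L
      while (at <= n) {
        hi <- min(at + cfg@batchSize - 1L, n)
        sel <- perm[at:hi]
        fw <- nnForward(layers, tr$X[, , , sel, drop = FALSE], cfg@activation,
                        training = TRUE, keepCaches = TRUE)
        epLoss <- epLoss + crossEntropy(fw$P, tr$y[sel]) * length(sel)
        epCorrect <- epCorrect + sum(max.col(t(fw$P), ties.method = "first") == tr$y[sel])
        grads <- nnBackward(layers, fw, tr$y[sel], cfg@activation)
        t <- t + 1L
        upd <- adamStep(layers, grads, state, cfg@learningRate, t)
        layers <- upd$layers
        state <- upd$state
        at <- hi + 1L
      }
      classifier@layers <- layers
      evTe <- evalOnSet(classifier, dataset@test)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epLoss / n,
                                  trainAccuracy = epCorrect / n,
                                  testLoss = evTe$loss, testAccuracy = evTe$acc)
      if (verbose)
        message(sprintf("epoch %3d: train loss %.4f acc %.4f | test loss %.4f acc %.4f",
                        epoch, epLoss / n, epCorrect / n, evTe$loss, evTe$acc))
    }
  })
  classifier@layers <- layers
  classifier@trained <- TRUE
  history <- do.call(rbind, hist)
  # final reported metrics come from full evaluation passes (dropout off)
  evTr <- evalOnSet(classifier, dataset@train)
  evTe <- evalOnSet(classifier, dataset@test)
  new("TrainResult", config = cfg, classifier = classifier,
      trainLoss = evTr$loss, trainAccuracy = evTr$acc,
      testLoss = evTe$loss, testAccuracy = evTe$acc,
      history = history)
}

#' @rdname trainingHistory
#' @param x a [TrainResult-class] or [InstanceSegmenter-class].
#' @export
setMethod("trainingHistory", "TrainResult", function(x) x@history)

setMethod("show", "TrainResult", function(object) {
  cfg <- object@config
  cat(sprintf("TrainResult: %s/%d epochs/depth %d/dropout %.2f -> train %.4f (loss %.4f), test %.4f (loss %.4f)\n",
              cfg@activation, cfg@epochs, cfg@nLayers, cfg@dropoutRate,
              object@trainAccuracy, object@trainLoss,
              object@testAccuracy, object@testLoss))
})

#' Score a whole image window by window
#'
#' Tiles the image (non-overlapping grid by default) and records the
#' nucleus-class probability of each window.
#'
#' @param classifier a trained [PatchClassifier-class] or a
#'   [TrainResult-class].
#' @param image RGB array, at least `96 x 96`.
#' @param stride tiling stride; defaults to the window size.
#' @param sourceId image identifier recorded in the map.
#' @return a [ProbabilityMap-class].
#' @export
scoreImage <- function(classifier, image, stride = NULL, sourceId = "image") {
  if (is(classifier, "TrainResult")) classifier <- classifier@classifier
  if (!classifier@trained) stop("classifier has not been trained")
  w <- classifier@inputSize
  if (is.null(stride)) stride <- w
  tl <- tileImage(image, window = w, stride = stride)
  P <- predictPatchProbs(classifier, tl$patches)
  new("ProbabilityMap",
      map = data.frame(row0 = tl$origins[, 1], col0 = tl$origins[, 2],
                       prob = P[, "nucleus"]),
      window = as.integer(w), imageSize = as.integer(dim(image)[1:2]),
      sourceId = sourceId)
}

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap '%s': %d windows of %d px on %d x %d image; prob range [%.3f, %.3f]\n",
              object@sourceId, nrow(object@map), object@window,
              object@imageSize[1], object@imageSize[2],
              min(object@map$prob), max(object@map$prob)))
})

#' Overlay window probabilities on an image
#'
#' Windows with nucleus probability strictly above `redThreshold` are
#' tinted red; probabilities strictly above `yellowThreshold` (but not
#' above `redThreshold`) are tinted yellow; all other windows are left
#' untouched. Thresholds are strict, so a probability exactly equal to
#' `redThreshold` is yellow and one equal to `yellowThreshold` is
#' untinted.
#'
#' @param image RGB array the map was computed on.
#' @param pmap a [ProbabilityMap-class].
#' @param redThreshold,yellowThreshold tint thresholds with
#'   `0 <= yellowThreshold < redThreshold <= 1`.
#' @param alpha tint opacity in `(0, 1]`.
#' @return tinted RGB array (same shape as `image`).
#' @export
renderOverlay <- function(image, pmap, redThreshold = 0.9, yellowThreshold = 0.5,
                          alpha = 0.4) {
  if (!(yellowThreshold >= 0 && yellowThreshold < redThreshold && redThreshold <= 1))
    stop("thresholds must satisfy 0 <= yellowThreshold < redThreshold <= 1")
  w <- pmap@window
  out <- image
  tints <- list(red = c(1, 0, 0), yellow = c(1, 1, 0))
  for (i in seq_len(nrow(pmap@map))) {
    p <- pmap@map$prob[i]
    tint <- if (p > redThreshold) tints$red
            else if (p > yellowThreshold) tints$yellow
            else next
    r <- pmap@map$row0[i]; c <- pmap@map$col0[i]
    rows <- (r + 1L):(r + w); cols <- (c + 1L):(c + w)
    for (ch in 1:3) {
      out[rows, cols, ch] <- (1 - alpha) * image[rows, cols, ch] + alpha * tint[ch]
    }
  }
  out
}

# ---- configuration grid ----------------------------------------------------

#' Rank grid results and flag overlearning
#'
#' A configuration is flagged as overlearned when its train accuracy
#' exceeds its test accuracy by more than `overfitGap`. Non-overlearned
#' configurations are ranked by test accuracy (rank 1 best); overlearned
#' ones get rank `NA`.
#'
#' @param results list of [TrainResult-class] objects.
#' @param overfitGap gap threshold (default 0.05).
#' @return data.frame mirroring a grid-report table: configuration
#'   columns, final losses and accuracies, `overlearned`, `rank`.
#' @export
gridReport <- function(results, overfitGap = 0.05) {
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    cfg <- r@config
    data.frame(no = i, activation = cfg@activation, epochs = cfg@epochs,
               nLayers = cfg@nLayers, dropout = cfg@dropoutRate,
               trainLoss = r@trainLoss, trainAccuracy = r@trainAccuracy,
               testLoss = r@testLoss, testAccuracy = r@testAccuracy)
  }))
  df$overlearned <- (df$trainAccuracy - df$testAccuracy) > overfitGap
  df$rank <- NA_integer_
  ok <- which(!df$overlearned)
  df$rank[ok[order(-df$testAccuracy[ok])]] <- seq_along(ok)
  df
}

#' Train every configuration of a grid on the same dataset
#'
#' @param dataset a [WindowDataset-class] (same splits for every cell).
#' @param grid list of [PatchClassifierConfig-class]; defaults to the
#'   9-row [defaultConfigGrid()].
#' @param overfitGap overlearning flag threshold.
#' @param verbose print progress.
#' @return list with `results` (list of [TrainResult-class]) and `report`
#'   (the [gridReport()] data.frame).
#' @export
runConfigGrid <- function(dataset, grid = defaultConfigGrid(), overfitGap = 0.05,
                          verbose = FALSE) {
  if (!length(grid)) stop("grid must contain at least one configuration")
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    if (verbose) message(sprintf("grid %d/%d", i, length(grid)))
    results[[i]] <- trainPatchClassifier(buildPatchClassifier(grid[[i]]),
                                         dataset, verbose = verbose)
  }
  list(results = results, report = gridReport(results, overfitGap))
}

#' Best non-overlearned grid result
#' @param gridRun value of [runConfigGrid()].
#' @return the rank-1 [TrainResult-class] (errors when every configuration
#'   overlearned).
#' @export
bestGridResult <- function(gridRun) {
  rk <- gridRun$report$rank
  if (all(is.na(rk))) stop("every configuration was flagged as overlearned")
  gridRun$results[[which(rk == 1L)]]
}

#' Save / load a trained classifier
#'
#' The checkpoint is a serialized weight file with a JSON sidecar carrying
#' the configuration.
#'
#' @param result a [TrainResult-class] or [PatchClassifier-class].
#' @param path checkpoint path (`.rds`); the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `saveClassifier`: (invisibly) the checkpoint path;
#'   `loadClassifier`: a [PatchClassifier-class].
#' @export
saveClassifier <- function(result, path) {
  cl <- if (is(result, "TrainResult")) result@classifier else result
  saveRDS(cl, path)
  cfg <- cl@config
  jsonlite::write_json(
    list(activation = cfg@activation, epochs = cfg@epochs,
         nLayers = cfg@nLayers, dropoutRate = cfg@dropoutRate,
         learningSeed = cfg@learningSeed, batchSize = cfg@batchSize,
         learningRate = cfg@learningRate, inputSize = cl@inputSize,
         trained = cl@trained),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) readRDS(path)
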