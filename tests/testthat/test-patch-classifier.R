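# Patch-classifier training behaviour, whole-image scoring, the overlay
# semantics and the configuration-grid report.

# one small trained classifier shared by several blocks
localTrained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scenes <- easyScenes(8, seedBase = 5000L)
      ws <- assembleBalancedDataset(scenes, nPerClass = 24L, seed = 5)
      dset <- splitDataset(ws, 0.75, seed = 6)
      cfg <- patchClassifierConfig("ReLU", epochs = 5L, nLayers = 18L,
                                   dropoutRate = 0.25)
      cache <<- list(result = trainPatchClassifier(buildPatchClassifier(cfg), dset),
                     dataset = dset)
    }
    cache
  }
})

test_that("training reduces loss, fills the history, and is reproducible", {
  tr <- localTrained()
  res <- tr$result
  h <- trainingHistory(res)
  expect_identical(nrow(h), 5L)
  expect_lt(h$trainLoss[5], h$trainLoss[1])
  expect_true(all(c(res@trainAccuracy, res@testAccuracy) >= 0 &
                    c(res@trainAccuracy, res@testAccuracy) <= 1))
  res2 <- trainPatchClassifier(buildPatchClassifier(res@config), tr$dataset)
  expect_identical(trainingHistory(res2), h)
})

test_that("one epoch on constant-label data yields perfect train accuracy", {
  scenes <- easyScenes(4, seedBase = 5300L)
  ws <- assembleBalancedDataset(scenes, nPerClass = 16L, seed = 9)
  onlyNuc <- cytodetect:::subsetWindowSet(ws, which(windowInfo(ws)$label == "nucleus"))
  dsetNuc <- new("WindowDataset",
                 train = cytodetect:::subsetWindowSet(onlyNuc, 1:12),
                 test = cytodetect:::subsetWindowSet(onlyNuc, 13:16),
                 splitSeed = 1L,
                 classCounts = rbind(train = c(nucleus = 12L),
                                     test = c(nucleus = 4L)))
  cfg <- patchClassifierConfig("ReLU", epochs = 1L, nLayers = 18L,
                               dropoutRate = 0, batchSize = 4L)
  res <- trainPatchClassifier(buildPatchClassifier(cfg), dsetNuc)
  expect_identical(res@trainAccuracy, 1)
  expect_identical(nrow(trainingHistory(res)), 1L)
})

test_that("whole-image scoring emits one probability per grid window", {
  tr <- localTrained()
  scene <- smallScene(5150)
  pmap <- scoreImage(tr$result, sceneImage(scene), sourceId = "s")
  tl <- tileImage(sceneImage(scene), extract = FALSE)
  expect_identical(nrow(pmap@map), nrow(tl$origins))
  expect_true(all(pmap@map$prob >= 0 & pmap@map$prob <= 1))
  expect_error(scoreImage(buildPatchClassifier(tr$result@config),
                          sceneImage(scene)), "trained")
})

test_that("overlay thresholds are strict and rendering is idempotent", {
  img <- array(0.5, dim = c(192L, 192L, 3L))
  pmap <- new("ProbabilityMap",
              map = data.frame(row0 = c(0L, 0L, 96L, 96L),
                               col0 = c(0L, 96L, 0L, 96L),
                               prob = c(0.95, 0.60, 0.40, 0.90)),
              window = 96L, imageSize = c(192L, 192L), sourceId = "fixture")
  ov <- renderOverlay(img, pmap)
  px <- function(r, c) ov[r, c, ]
  expect_true(px(48, 48)[1] > 0.6 && px(48, 48)[3] < 0.4)     # red tint
  expect_true(all(px(48, 144)[1:2] > 0.6) && px(48, 144)[3] < 0.4)  # yellow tint
  expect_identical(px(144, 48), c(0.5, 0.5, 0.5))             # untinted
  expect_true(all(px(144, 144)[1:2] > 0.6))                   # p = 0.9 exactly -> yellow
  expect_identical(renderOverlay(img, pmap), ov)              # idempotent
  expect_error(renderOverlay(img, pmap, redThreshold = 0.4, yellowThreshold = 0.5),
               "thresholds")
})

test_that("the grid report flags overlearning and ranks by test accuracy", {
  mkRes <- function(cfg, trAcc, teAcc) {
    h <- data.frame(epoch = seq_len(cfg@epochs), trainLoss = 0.1,
                    trainAccuracy = trAcc, testLoss = 0.2, testAccuracy = teAcc)
    new("TrainResult", config = cfg,
        classifier = buildPatchClassifier(cfg),
        trainLoss = 0.1, trainAccuracy = trAcc, testLoss = 0.2,
        testAccuracy = teAcc, history = h)
  }
  cfg <- patchClassifierConfig("ReLU", epochs = 2L)
  results <- list(mkRes(cfg, 0.956, 0.931),   # clean
                  mkRes(cfg, 0.998, 0.891),   # overlearned at gap 0.05
                  mkRes(cfg, 0.925, 0.921))
  rep <- gridReport(results, overfitGap = 0.05)
  expect_identical(rep$overlearned, c(FALSE, TRUE, FALSE))
  expect_identical(rep$rank, c(1L, NA_integer_, 2L))
  expect_error(runConfigGrid(localTrained()$dataset, list()), "at least one")
})

test_that("the default grid enumerates the nine documented configurations", {
  grid <- defaultConfigGrid()
  expect_length(grid, 9L)
  tab <- t(vapply(grid, function(g)
    c(g@activation, g@epochs, g@nLayers, g@dropoutRate), character(4)))
  expect_identical(tab[2, ], c("ReLU", "20", "18", "0.25"))
  expect_identical(tab[9, 1], "Sigmoid")
  expect_identical(sum(tab[, 3] == "24"), 3L)
  expect_identical(sum(tab[, 4] == "0.5"), 2L)
})

test_that("a single-config grid run trains and reports one ranked row", {
  tr <- localTrained()
  cfg <- patchClassifierConfig("ReLU", epochs = 2L, nLayers = 18L,
                               dropoutRate = 0.25)
  run <- runConfigGrid(tr$dataset, list(cfg), overfitGap = 1)
  expect_identical(nrow(run$report), 1L)
  expect_identical(run$report$rank, 1L)
  expect_s4_class(bestGridResult(run), "TrainResult")
})

test_that("classifier checkpoints round-trip through disk", {
  tr <- localTrained()
  path <- withr::local_tempfile(fileext = ".rds")
  saveClassifier(tr$result, path)
  expect_true(file.exists(paste0(path, ".json")))
  cl <- loadClassifier(path)
  scene <- smallScene(5601)
  expect_identical(scoreImage(cl, sceneImage(scene))@map,
                   scoreImage(tr$result, sceneImage(scene))@map)
})
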