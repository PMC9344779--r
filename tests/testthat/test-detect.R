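# Instance detection: the hue-threshold reference detector, NMS, and the
# trainable pixel-classifier backend.

test_that("the hue oracle finds every blue nucleus and nothing else", {
  for (seed in c(61, 62, 63)) {
    scene <- smallScene(seed)
    dset <- oracleDetect(sceneImage(scene), sourceId = scene@id)
    expect_identical(length(dset), sum(lineages(scene) == "blue"))
    mr <- matchDetections(dset, scene, mode = "instance")
    expect_identical(mr@nBackground, 0L)
    expect_identical(mr@nUndetected, 0L)
  }
})

test_that("an all-red scene yields no oracle detections", {
  scene <- generateScene(sceneConfig(nBlue = 0L, nRed = 6L,
                                     imageSize = c(288L, 384L), seed = 70))
  expect_identical(length(oracleDetect(sceneImage(scene))), 0L)
})

test_that("oracle detection counts are invariant to mild brightness shifts", {
  scene <- smallScene(71)
  base <- length(oracleDetect(sceneImage(scene)))
  for (shift in c(-0.04, 0.04)) {
    img <- sceneImage(scene) + shift
    img[img < 0] <- 0; img[img > 1] <- 1
    expect_identical(length(oracleDetect(img)), base)
  }
})

test_that("detection masks stay inside their boxes and NMS is idempotent", {
  scene <- smallScene(72)
  dset <- oracleDetect(sceneImage(scene))
  for (d in detections(dset)) {
    expect_identical(dim(d@mask),
                     c(d@box[3] - d@box[1], d@box[4] - d@box[2]))
    expect_true(any(d@mask[1, ]) || any(d@mask[nrow(d@mask), ]))  # tight box
  }
  # overlapping synthetic detections: high scorer suppresses low scorer
  m <- matrix(TRUE, 10, 10)
  a <- detection(m, box = c(0L, 0L, 10L, 10L), score = 0.9)
  b <- detection(m, box = c(2L, 2L, 12L, 12L), score = 0.6)   # IoU 64/136
  c <- detection(m, box = c(40L, 40L, 50L, 50L), score = 0.5)
  kept <- nmsFilter(list(a, b, c), nmsThreshold = 0.4)
  expect_length(kept, 2L)
  expect_identical(nmsFilter(kept, nmsThreshold = 0.4), kept)
  keptLoose <- nmsFilter(list(a, b, c), nmsThreshold = 0.5)
  expect_length(keptLoose, 3L)
})

test_that("the pixel segmenter trains, validates, and detects cleanly", {
  pairs <- lapply(easyScenes(5, seedBase = 6000L), sceneToTrainingPair)
  seg <- trainInstanceSegmenter(pairs, epochs = 8L, seed = 3)
  h <- trainingHistory(seg)
  expect_identical(nrow(h), 8L)
  expect_lt(h$valLoss[8], h$valLoss[1])
  seg2 <- trainInstanceSegmenter(pairs, epochs = 8L, seed = 3)
  expect_identical(trainingHistory(seg2), h)

  scene <- smallScene(6100, nBlue = 8L, nRed = 4L)
  dset <- detectNuclei(seg, sceneImage(scene), sourceId = scene@id)
  expect_identical(length(dset), 8L)
  mr <- matchDetections(dset, scene, mode = "instance")
  expect_identical(mr@nBackground, 0L)
  expect_identical(mr@nUndetected, 0L)

  # background-only image: at most a trivial false-positive budget
  bg <- generateScene(sceneConfig(nBlue = 0L, nRed = 0L,
                                  imageSize = c(288L, 384L), seed = 77))
  expect_lte(length(detectNuclei(seg, sceneImage(bg))), 1L)

  # raising the score threshold never increases the detection count
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(thr)
    length(detectNuclei(seg, sceneImage(scene), scoreThreshold = thr)),
    integer(1))
  expect_true(all(diff(counts) <= 0L))

  expect_error(detectNuclei(new("InstanceSegmenter", weights = numeric(8),
                                history = data.frame(), trained = FALSE,
                                params = list(pixelThreshold = 0.5)),
                            sceneImage(scene)), "trained")
  expect_error(trainInstanceSegmenter(list()), "no training pairs")
  # images without masks are allowed only alongside at least one masked pair
  blank <- maskTrainingPair(sceneImage(bg), matrix(0L, 288, 384))
  expect_error(trainInstanceSegmenter(list(blank)), "instance mask")
  segMixed <- trainInstanceSegmenter(c(pairs, list(blank)), epochs = 2L, seed = 1)
  expect_s4_class(segMixed, "InstanceSegmenter")
})

test_that("window detections carry the yellow-band strictness", {
  pmap <- new("ProbabilityMap",
              map = data.frame(row0 = c(0L, 96L, 0L), col0 = c(0L, 0L, 96L),
                               prob = c(0.51, 0.5, 0.95)),
              window = 96L, imageSize = c(192L, 192L), sourceId = "s")
  dset <- windowDetections(pmap, threshold = 0.5)
  expect_identical(length(dset), 2L)    # p = 0.5 exactly is excluded
  expect_true(all(detectionScores(dset) > 0.5))
  expect_identical(dim(detections(dset)[[1]]@mask), c(96L, 96L))
})
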