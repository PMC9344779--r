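# Synthetic cytology scene generator: counts, determinism, colour bands,
# ground-truth consistency and export round-trips.

test_that("generated scenes have the requested composition", {
  cfg <- smallSceneConfig(7, nBlue = 5L, nRed = 3L)
  scene <- generateScene(cfg)
  lin <- lineages(scene)
  expect_length(sceneInstances(scene), 8L)
  expect_identical(sum(lin == "blue"), 5L)
  expect_identical(sum(lin == "red"), 3L)
  expect_identical(dim(sceneImage(scene)), c(288L, 384L, 3L))

  empty <- generateScene(sceneConfig(nBlue = 0L, nRed = 0L, debrisDensity = 0,
                                     stainNoiseSd = 0, imageSize = c(100L, 120L),
                                     seed = 1))
  expect_length(sceneInstances(empty), 0L)
  # uniform background: one colour per channel
  expect_lte(length(unique(as.numeric(sceneImage(empty)))), 3L)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- smallSceneConfig(11)
  a <- generateScene(cfg)
  b <- generateScene(cfg)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(labelMask(a), labelMask(b))
  c <- generateScene(smallSceneConfig(12))
  expect_false(identical(sceneImage(a), sceneImage(c)))
})

test_that("impossible placement densities raise a capacity error", {
  cfg <- sceneConfig(nBlue = 50L, nRed = 0L, imageSize = c(120L, 120L),
                     nucleusRadiusRange = c(12, 16), seed = 1)
  expect_error(generateScene(cfg), class = "cytodetectCapacityError")
})

test_that("instance masks are in-bounds, disjoint, and visibly stained", {
  for (seed in c(3, 14, 15)) {
    scene <- smallScene(seed)
    d <- dim(sceneImage(scene))
    total <- matrix(0L, d[1], d[2])
    for (inst in sceneInstances(scene)) {
      expect_gte(sum(inst@mask), 20L)
      expect_true(inst@box[1] >= 0L && inst@box[2] >= 0L &&
                    inst@box[3] <= d[1] && inst@box[4] <= d[2])
      total <- total + instanceMask(scene, inst@id)
    }
    expect_lte(max(total), 1L)  # overlapFraction = 0 => disjoint masks
    # nucleus pixels differ from the background colour by far more than
    # the stain noise level
    bgGreen <- 0.94
    g <- sceneImage(scene)[, , 2]
    for (inst in sceneInstances(scene)) {
      m <- instanceMask(scene, inst@id)
      expect_true(all(abs(g[m] - bgGreen) > scene@config@stainNoiseSd))
    }
  }
})

test_that("lineage hue bands are disjoint and respected across an ensemble", {
  bands <- stainHueBands()
  for (seed in 101:130) {
    scene <- generateScene(sceneConfig(nBlue = 2L, nRed = 2L,
                                       imageSize = c(160L, 200L), seed = seed))
    hsv <- rgbToHsv(sceneImage(scene))
    for (inst in sceneInstances(scene)) {
      m <- instanceMask(scene, inst@id)
      mh <- mean(hsv$h[m])
      if (inst@lineage == "blue") {
        expect_true(mh >= bands$blue[1] && mh <= bands$blue[2])
      } else {
        expect_true(mh >= bands$red[1] || mh <= bands$red[2])
      }
    }
  }
})

test_that("ground-truth export writes a complete, lossless bundle", {
  scene <- smallScene(21)
  dir <- withr::local_tempdir()
  man <- exportGroundTruth(scene, dir)
  expect_true(all(file.exists(man$path)))
  # one mask per instance + image tiff/png + labels + annotations + manifest entries
  expect_identical(sum(grepl("instance_mask", man$kind)), length(sceneInstances(scene)))

  lab <- tiff::readTIFF(man$path[man$kind == "label_mask_tiff16"])
  ids <- round(lab * 65535)
  areasFile <- as.integer(table(ids[ids > 0]))
  areasMem <- vapply(sceneInstances(scene), function(i) sum(i@mask), integer(1))
  expect_identical(areasFile, areasMem)

  ann <- jsonlite::read_json(man$path[man$kind == "annotations_json"])
  expect_length(ann$annotations, length(sceneInstances(scene)))
  cats <- vapply(ann$annotations, function(a) a$category_id, numeric(1))
  expect_identical(sum(cats == 1), sum(lineages(scene) == "blue"))

  emptyDir <- withr::local_tempdir()
  empty <- generateScene(sceneConfig(nBlue = 0L, nRed = 0L,
                                     imageSize = c(96L, 96L), seed = 2))
  manE <- exportGroundTruth(empty, emptyDir)
  annE <- jsonlite::read_json(manE$path[manE$kind == "annotations_json"])
  expect_length(annE$annotations, 0L)
})
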