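# Matched-region accounting and the four comparison criteria.

test_that("count-level metric arithmetic matches hand calculations", {
  m <- computeMetrics(matchResult(320L, 97L, 36L, 67L))
  expect_identical(m@backgroundFraction, 0.3031)
  expect_identical(m@avgUndetected, 1.8611)
  expect_identical(m@avgRegions, roundHalfUp(223 / 36, 4))
  expect_identical(computeMetrics(matchResult(37L, 1L, 36L, 0L), decimals = 3L)@backgroundFraction,
                   0.027)
  clean <- computeMetrics(matchResult(37L, 0L, 36L, 0L))
  expect_identical(clean@backgroundFraction, 0)
  # D = 0 convention and N = 0 error
  expect_identical(computeMetrics(matchResult(0L, 0L, 5L, 5L))@backgroundFraction, 0)
  expect_error(computeMetrics(matchResult(3L, 1L, 0L, 0L)), "nucleus")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_identical(roundHalfUp(0.303125, 4L), 0.3031)
  expect_identical(roundHalfUp(0.00005, 4L), 1e-4)
  expect_identical(roundHalfUp(-0.00005, 4L), -1e-4)
  expect_identical(roundHalfUp(1 / 37, 3L), 0.027)
})

test_that("a perfect detector is a fixed point of the matching", {
  scene <- smallScene(81)
  dset <- oracleDetect(sceneImage(scene), sourceId = scene@id)
  m <- computeMetrics(matchDetections(dset, scene, mode = "instance"))
  expect_identical(m@backgroundFraction, 0)
  expect_identical(m@avgUndetected, 0)
  expect_identical(m@avgRegions, 1)
})

test_that("empty detection sets count every expected region as undetected", {
  scene <- smallScene(82)
  nBlue <- sum(lineages(scene) == "blue")
  dset <- cytodetect:::newDetectionSet(list(), sourceId = scene@id)
  mr <- matchDetections(dset, scene, mode = "instance")
  expect_identical(mr@nDetections, 0L)
  expect_identical(mr@nBackground, 0L)
  expect_identical(mr@nUndetected, nBlue)
})

test_that("a stray detection increments B and D but never U", {
  scene <- smallScene(83)
  dset <- oracleDetect(sceneImage(scene), sourceId = scene@id)
  base <- matchDetections(dset, scene, mode = "instance")
  stray <- detection(matrix(TRUE, 6L, 6L), box = c(0L, 0L, 6L, 6L), score = 1)
  dset2 <- cytodetect:::newDetectionSet(c(detections(dset), list(stray)),
                                        sourceId = scene@id)
  withStray <- matchDetections(dset2, scene, mode = "instance")
  expect_identical(withStray@nDetections, base@nDetections + 1L)
  expect_identical(withStray@nBackground, base@nBackground + 1L)
  expect_identical(withStray@nUndetected, base@nUndetected)
})

test_that("matching agrees with brute-force enumeration and conserves counts", {
  withr::with_seed(90, {
    for (rep in 1:15) {
      scene <- smallScene(8300 + rep, nBlue = sample(2:6, 1), nRed = 2L)
      # perturbed detections: oracle masks plus random strays and drops
      dets <- detections(oracleDetect(sceneImage(scene), sourceId = scene@id))
      if (length(dets) > 1 && runif(1) < 0.5) dets <- dets[-1]
      nStray <- sample(0:3, 1)
      d <- dim(sceneImage(scene))
      for (s in seq_len(nStray)) {
        r <- sample(0:(d[1] - 12L), 1); c <- sample(0:(d[2] - 12L), 1)
        dets <- c(dets, list(detection(matrix(TRUE, 12L, 12L),
                                       box = c(r, c, r + 12L, c + 12L),
                                       score = runif(1, 0.5, 1))))
      }
      dset <- cytodetect:::newDetectionSet(dets, sourceId = scene@id)
      fast <- matchDetections(dset, scene, mode = "instance")
      slow <- bruteMatchInstance(dset, scene)
      expect_identical(fast@nDetections, slow$D)
      expect_identical(fast@nBackground, slow$B)
      expect_identical(fast@nUndetected, slow$U)
      expect_identical(fast@perNucleus$regions, slow$regions)
      # conservation
      expect_identical(fast@nBackground + fast@nMatched, fast@nDetections)
    }
  })
})

test_that("window-mode matching counts expected and detected grid windows", {
  scene <- smallScene(85)
  tl <- tileImage(sceneImage(scene), extract = FALSE)
  labels <- lapply(seq_len(nrow(tl$origins)),
                   function(i) labelWindow(tl$origins[i, ], scene))
  pos <- which(vapply(labels, function(l) l$label == "nucleus", logical(1)))
  # a probability map that "detects" every positive window
  pmap <- new("ProbabilityMap",
              map = data.frame(row0 = tl$origins[, 1], col0 = tl$origins[, 2],
                               prob = ifelse(seq_len(nrow(tl$origins)) %in% pos,
                                             0.95, 0.05)),
              window = 96L, imageSize = dim(sceneImage(scene))[1:2],
              sourceId = scene@id)
  mr <- matchDetections(windowDetections(pmap, 0.5), scene, mode = "window")
  expect_identical(mr@nUndetected, 0L)
  expect_identical(mr@nDetections, length(pos))
  expect_identical(sum(mr@perNucleus$expected),
                   sum(vapply(labels, function(l) length(l$coveredIds), integer(1))))
  # silent map: every expected window becomes undetected
  silent <- new("ProbabilityMap",
                map = data.frame(row0 = tl$origins[, 1], col0 = tl$origins[, 2],
                                 prob = rep(0.01, nrow(tl$origins))),
                window = 96L, imageSize = dim(sceneImage(scene))[1:2],
                sourceId = scene@id)
  mr0 <- matchDetections(windowDetections(silent, 0.5), scene, mode = "window")
  expect_identical(mr0@nUndetected, sum(mr@perNucleus$expected))
})

test_that("comparison tables mirror the four-criterion layout", {
  swm <- matchResult(320L, 97L, 36L, 67L)
  inst <- matchResult(37L, 1L, 36L, 0L)
  tab <- compareBackends(swm, inst, names = c("Sliding window", "Mask-style"))
  expect_identical(dim(tab), c(4L, 3L))
  expect_identical(tab[["Sliding window"]][2], "0.3031 (97/320)")
  expect_identical(tab[["Sliding window"]][3], "1.8611 (67/36)")
  expect_identical(tab[["Sliding window"]][4], "6.1944 (223/36)")
  expect_identical(tab[["Mask-style"]][4], "1 (36/36)")
  # identical inputs -> identical columns; swapped inputs -> swapped columns
  same <- compareBackends(swm, swm)
  expect_identical(same[[2]], same[[3]])
  swapped <- compareBackends(inst, swm, names = c("b", "a"))
  expect_identical(swapped[["b"]], tab[["Mask-style"]])
  expect_identical(swapped[["a"]], tab[["Sliding window"]])
})

test_that("combining match results pools counts and rejects mixed modes", {
  sceneA <- smallScene(86)
  sceneB <- smallScene(87)
  mA <- matchDetections(oracleDetect(sceneImage(sceneA), sourceId = "a"), sceneA)
  mB <- matchDetections(oracleDetect(sceneImage(sceneB), sourceId = "b"), sceneB)
  pooled <- combineMatchResults(list(mA, mB))
  expect_identical(pooled@nDetections, mA@nDetections + mB@nDetections)
  expect_identical(pooled@nNuclei, mA@nNuclei + mB@nNuclei)
  expect_identical(pooled@sourceIds, c("a", "b"))
  wA <- new("MatchResult", nDetections = 1L, nBackground = 0L, nNuclei = 1L,
            nUndetected = 0L, nMatched = 1L, perNucleus = data.frame(),
            sourceIds = "a", mode = "window")
  expect_error(combineMatchResults(list(mA, wA)), "different modes")
  expect_error(compareBackends(mA, mB), "different image sets")
})
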