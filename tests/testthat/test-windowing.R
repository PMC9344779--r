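# Tiling geometry, the blue-lineage coverage labelling rule, balanced
# assembly and the stratified split.

test_that("tiling follows the floor(H/stride) x floor(W/stride) grid", {
  img <- array(0.5, dim = c(1024L, 1280L, 3L))
  tl <- tileImage(img, extract = FALSE)
  expect_identical(nrow(tl$origins), 130L)        # 10 x 13
  expect_identical(tl$origins[1, ], c(row0 = 0L, col0 = 0L))

  one <- tileImage(array(0, c(96L, 96L, 3L)))
  expect_identical(nrow(one$origins), 1L)
  expect_identical(dim(one$patches), c(96L, 96L, 3L, 1L))

  expect_error(tileImage(array(0, c(95L, 95L, 3L))), "larger than image")

  withr::with_seed(9, {
    for (i in 1:20) {
      H <- sample(96:400, 1); W <- sample(96:400, 1)
      win <- sample(16:96, 1); stride <- sample(8:win, 1)
      tl <- tileImage(array(0, c(H, W, 3L)), window = win, stride = stride,
                      extract = FALSE)
      expect_identical(nrow(tl$origins),
                       length(seq.int(0L, H - win, stride)) *
                         length(seq.int(0L, W - win, stride)))
      expect_true(all(tl$origins[, 1] + win <= H))
      expect_true(all(tl$origins[, 2] + win <= W))
    }
  })
})

test_that("extracted patches equal the image content at their origin", {
  scene <- smallScene(31)
  tl <- tileImage(sceneImage(scene))
  i <- 5L
  r <- tl$origins[i, 1]; c <- tl$origins[i, 2]
  expect_identical(tl$patches[, , , i],
                   sceneImage(scene)[(r + 1):(r + 96), (c + 1):(c + 96), ])
})

test_that("window labels agree with brute-force pixel counting", {
  for (seed in c(41, 42)) {
    scene <- smallScene(seed)
    tl <- tileImage(sceneImage(scene), extract = FALSE)
    for (i in seq_len(nrow(tl$origins))) {
      fast <- labelWindow(tl$origins[i, ], scene)
      slow <- bruteLabelWindow(tl$origins[i, ], scene)
      expect_identical(fast$label, slow$label)
      expect_identical(sort(fast$coveredIds), sort(slow$coveredIds))
    }
  }
})

test_that("the coverage rule is strict and blue-only", {
  # rectangle mask 20 x 40 px spanning the window boundary at column 96:
  # exactly half (20 x 20 = 400 px) falls inside the first window
  scene <- rectangleScene(11:30, 77:116)
  lw <- labelWindow(c(0L, 0L), scene)
  expect_identical(lw$label, "non_nucleus")       # exactly 50% is not "more than half"

  # one extra in-window pixel tips the fraction above 1/2
  scenePlus <- rectangleScene(11:30, 77:116, extraPixel = c(10L, 76L))
  lwPlus <- labelWindow(c(0L, 0L), scenePlus)
  expect_identical(lwPlus$label, "nucleus")
  expect_identical(lwPlus$coveredIds, 1L)

  # the same geometry in red lineage never labels positive
  m <- matrix(FALSE, 192L, 192L); m[11:30, 20:59] <- TRUE
  img <- array(0.94, dim = c(192L, 192L, 3L))
  redScene <- syntheticScene(img, list(nucleusInstance(1L, "red", m)), id = "red")
  expect_identical(labelWindow(c(0L, 0L), redScene)$label, "non_nucleus")

  expect_error(labelWindow(c(100L, 100L), scene), "inside the scene")
})

test_that("balanced assembly draws exact class counts reproducibly", {
  scenes <- easyScenes(6, seedBase = 4100L)
  ws <- assembleBalancedDataset(scenes, nPerClass = 15L, seed = 5)
  expect_length(ws, 30L)
  tab <- table(windowInfo(ws)$label)
  expect_identical(as.integer(tab[["nucleus"]]), 15L)
  expect_identical(as.integer(tab[["non_nucleus"]]), 15L)
  # label <-> coveredIds invariant
  expect_identical(windowInfo(ws)$label == "nucleus",
                   vapply(windowInfo(ws)$coveredIds, length, 1L) > 0L)

  ws2 <- assembleBalancedDataset(scenes, nPerClass = 15L, seed = 5)
  expect_identical(windowInfo(ws), windowInfo(ws2))
  expect_identical(ws@patches, ws2@patches)

  expect_length(assembleBalancedDataset(scenes, 0L), 0L)
  expect_error(assembleBalancedDataset(scenes, 10000L, seed = 1),
               "insufficient 'nucleus'")
})

test_that("lazy assembly from configs matches in-memory assembly", {
  cfgs <- lapply(1:4, function(i) smallSceneConfig(4200L + i, nBlue = 6L, nRed = 2L))
  scenes <- lapply(cfgs, generateScene)
  a <- assembleBalancedDataset(scenes, nPerClass = 8L, seed = 2)
  b <- assembleBalancedDataset(cfgs, nPerClass = 8L, seed = 2)
  expect_identical(windowInfo(a), windowInfo(b))
  expect_identical(a@patches, b@patches)
})

test_that("stratified split reproduces the 591/197 partition of 788 windows", {
  # synthetic stand-in samples: the split only uses labels and indices
  n <- 394L
  patches <- array(0, dim = c(96, 96, 3, 2L * n))
  ws <- new("WindowSet", patches = patches,
            info = data.frame(sourceId = rep("s", 2L * n),
                              row0 = seq_len(2L * n), col0 = 0L,
                              label = rep(c("nucleus", "non_nucleus"), each = n),
                              coveredIds = I(c(as.list(seq_len(n)),
                                               rep(list(integer()), n)))),
            window = 96L)
  ds <- splitDataset(ws, trainFraction = 0.75, seed = 3)
  expect_identical(length(trainSet(ds)), 591L)
  expect_identical(length(testSet(ds)), 197L)
  cc <- classCounts(ds)
  # stratification: per-label train fraction within 1/n of 0.75
  for (lab in colnames(cc)) {
    frac <- cc["train", lab] / sum(cc[, lab])
    expect_lt(abs(frac - 0.75), 1 / n)
  }
  # disjoint and conserving
  info <- windowInfo(ds)
  key <- paste(info$sourceId, info$row0, info$col0)
  expect_identical(anyDuplicated(key), 0L)
  expect_identical(nrow(info), 2L * n)
})

test_that("small and degenerate splits behave as documented", {
  mk <- function(labels) {
    new("WindowSet", patches = array(0, c(96, 96, 3, length(labels))),
        info = data.frame(sourceId = "s", row0 = seq_along(labels), col0 = 0L,
                          label = labels,
                          coveredIds = I(lapply(labels, function(l)
                            if (l == "nucleus") 1L else integer()))),
        window = 96L)
  }
  ds <- splitDataset(mk(rep(c("nucleus", "non_nucleus"), 2L)), 0.5, seed = 1)
  cc <- classCounts(ds)
  expect_true(all(cc == 1L))
  expect_error(splitDataset(mk(c("nucleus", "non_nucleus", "non_nucleus")), 0.75),
               "at least 2 samples")
  expect_error(splitDataset(mk(rep("nucleus", 4L)), 1.0), "trainFraction")
})

test_that("split sizes always sum to the input size", {
  withr::with_seed(10, {
    for (i in 1:10) {
      nPos <- sample(2:40, 1); nNeg <- sample(2:40, 1)
      labels <- c(rep("nucleus", nPos), rep("non_nucleus", nNeg))
      ws <- new("WindowSet", patches = array(0, c(96, 96, 3, length(labels))),
                info = data.frame(sourceId = "s", row0 = seq_along(labels),
                                  col0 = 0L, label = labels,
                                  coveredIds = I(lapply(labels, function(l)
                                    if (l == "nucleus") 1L else integer()))),
                window = 96L)
      f <- runif(1, 0.2, 0.8)
      ds <- splitDataset(ws, f, seed = i)
      expect_identical(length(trainSet(ds)) + length(testSet(ds)), nPos + nNeg)
    }
  })
})
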