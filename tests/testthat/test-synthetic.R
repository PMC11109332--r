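test_that("genCells produces disks with the requested class means", {
  sc <- genCells(nCells = 50, meanA = 80, meanB = 180, noiseSd = 5, seed = 3)
  img <- pixels(sceneImage(sc))[1, , ]
  msk <- maskLabels(sceneMask(sc))
  truth <- sceneTruth(sc)
  for (k in 1:2) {
    ids <- as.integer(names(truth)[truth == k])
    vals <- img[msk %in% ids]
    target <- c(80, 180)[k]
    expect_lt(abs(mean(vals) - target), 3 * 5 / sqrt(length(vals)))
  }
  # every mask id appears in truth, classes cover 1..2 (validity holds)
  expect_true(validObject(sc))
  expect_setequal(unique(truth), 1:2)
})

test_that("genCells: zero noise gives exactly constant interiors", {
  sc <- genCells(nCells = 20, noiseSd = 0, seed = 9)
  img <- pixels(sceneImage(sc))[1, , ]
  msk <- maskLabels(sceneMask(sc))
  truth <- sceneTruth(sc)
  for (id in objectIds(sceneMask(sc))) {
    vals <- unique(img[msk == id])
    expect_identical(vals, c(80, 180)[truth[as.character(id)]])
  }
})

test_that("generators are pure functions of parameters + seed", {
  expect_identical(genCells(seed = 5), genCells(seed = 5))
  expect_false(identical(pixels(sceneImage(genCells(seed = 5))),
                         pixels(sceneImage(genCells(seed = 6)))))
  expect_identical(genOrientedTextures(nTiles = 20, seed = 2),
                   genOrientedTextures(nTiles = 20, seed = 2))
  expect_identical(genBlobs3d(nBlobs = 8, seed = 4),
                   genBlobs3d(nBlobs = 8, seed = 4))
})

test_that("genCells reports the achieved count when placement fails", {
  expect_error(genCells(nCells = 500, canvas = c(64L, 64L), seed = 1),
               "placed")
})

test_that("oriented textures have matched moments but separable orientation", {
  sc <- genOrientedTextures(nTiles = 40, seed = 7)
  img <- pixels(sceneImage(sc))[1, , ]
  msk <- maskLabels(sceneMask(sc))
  truth <- sceneTruth(sc)
  means <- vars <- stat <- numeric(40)
  for (i in 1:40) {
    vals <- img[msk == i]
    means[i] <- mean(vals)
    vars[i] <- var(vals)
    stat[i] <- orientationEnergy(img, msk, i)
  }
  # per-tile mean and variance agree across classes to < 1% relative error
  expect_lt(max(abs(means - 128)) / 128, 0.01)
  expect_lt(max(abs(vars - 30^2)) / 30^2, 0.01)
  # brute-force oriented-gradient-energy statistic separates the classes
  a <- stat[truth == 1]
  b <- stat[truth == 2]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("oriented textures reject equal orientations and bad tiles", {
  expect_error(genOrientedTextures(thetaA = 45, thetaB = 225, seed = 1),
               "mod 180")
  expect_error(genOrientedTextures(tile = c(2L, 2L), seed = 1), "degenerate")
})

test_that("segregated layout puts the two classes in separate halves", {
  sc <- genOrientedTextures(nTiles = 36, seed = 2, layout = "segregated")
  truth <- sceneTruth(sc)
  cents <- objectCentroids(sceneMask(sc))
  x1 <- sapply(cents[names(truth)[truth == 1]], `[`, 2)
  x2 <- sapply(cents[names(truth)[truth == 2]], `[`, 2)
  expect_lt(max(x1), min(x2))
})

test_that("3D blobs separate by the configured rule", {
  sc <- genBlobs3d(nBlobs = 16, twoClassRule = "intensity", seed = 5)
  img <- pixels(sceneImage(sc))[1, , , ]
  msk <- maskLabels(sceneMask(sc))
  truth <- sceneTruth(sc)
  m1 <- sapply(names(truth)[truth == 1], function(id) mean(img[msk == as.integer(id)]))
  m2 <- sapply(names(truth)[truth == 2], function(id) mean(img[msk == as.integer(id)]))
  expect_true(max(m1) < min(m2))      # delta = 100 >> noise

  sc2 <- genBlobs3d(nBlobs = 16, twoClassRule = "elongation", seed = 5,
                    canvas = c(48L, 72L, 96L))
  msk2 <- maskLabels(sceneMask(sc2))
  t2 <- sceneTruth(sc2)
  ratio <- sapply(names(t2), function(id) {
    co <- which(msk2 == as.integer(id), arr.ind = TRUE)
    ext <- apply(co, 2, function(v) diff(range(v)) + 1)
    ext[3] / ext[1]                   # X extent over Z extent
  })
  r1 <- mean(ratio[t2 == 1]); r2 <- mean(ratio[t2 == 2])
  expect_gt(r2 / r1, 1.8)             # configured elongation factor 2.5

  one <- genBlobs3d(nBlobs = 1, seed = 2)
  expect_identical(objectIds(sceneMask(one)), 1L)
})

test_that("rotateScene90 preserves ids and truth while moving content", {
  sc <- genCells(nCells = 15, seed = 8, canvas = c(96L, 128L))
  rot <- rotateScene90(sc)
  expect_identical(sceneTruth(rot), sceneTruth(sc))
  expect_identical(dim(maskLabels(sceneMask(rot))), c(128L, 96L))
  expect_setequal(objectIds(sceneMask(rot)), objectIds(sceneMask(sc)))
  # per-object voxel counts unchanged by rotation
  t1 <- table(maskLabels(sceneMask(sc))[maskLabels(sceneMask(sc)) > 0])
  t2 <- table(maskLabels(sceneMask(rot))[maskLabels(sceneMask(rot)) > 0])
  expect_identical(t1, t2)
})

test_that("writeScene emits image, mask and truth in the annotation schema", {
  td <- withr::local_tempdir()
  sc <- genCells(nCells = 10, seed = 3, canvas = c(96L, 96L))
  paths <- writeScene(sc, td)
  expect_true(all(file.exists(paths)))
  truth <- readAnnotations(paths["truth"])
  expect_identical(nrow(annotations(truth)), 10L)
  back <- readLabelMask(paths["mask"])
  expect_identical(maskLabels(back), maskLabels(sceneMask(sc)))
})
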