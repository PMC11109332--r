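test_that("constant model predicts class 1 by tie-break with confidence 1/K", {
  pr <- tinyPair()
  spec <- tinySpec2d(nClasses = 4, patchSize = 8)
  m <- buildModel(spec, seed = 1)
  m@weights$head$V[] <- 0
  m@weights$head$c[] <- 0
  tab <- predictObjects(m, pr$image, pr$mask)
  expect_identical(nrow(tab), 2L)                    # one row per object
  expect_identical(tab$object_id, c(4L, 7L))
  expect_true(all(tab$class == 1L))
  expect_equal(tab$confidence, rep(0.25, 2), tolerance = 1e-12)
})

test_that("prediction is pure and covers every distinct mask id", {
  sc <- genCells(nCells = 30, seed = 3, canvas = c(160L, 160L))
  m <- buildModel(classifierSpec(2, 2, 8, 2, 2, 3, 16), seed = 5)
  t1 <- predictObjects(m, sceneImage(sc), sceneMask(sc))
  t2 <- predictObjects(m, sceneImage(sc), sceneMask(sc))
  expect_identical(t1, t2)
  expect_identical(t1$object_id, objectIds(sceneMask(sc)))
  expect_true(all(t1$confidence > 0 & t1$confidence <= 1))
})

test_that("channel mismatches are named", {
  pr <- tinyPair()
  m <- buildModel(tinySpec2d(inChannels = 3, patchSize = 8), seed = 1)
  expect_error(predictObjects(m, pr$image, pr$mask), "channel mismatch")
})

test_that("renderClassMask relabels voxelwise with identical support", {
  pr <- tinyPair()
  tab <- data.frame(image_id = "tiny", object_id = c(4L, 7L),
                    class = c(1L, 2L), confidence = 1)
  cm <- renderClassMask(pr$mask, tab)
  lab <- maskLabels(pr$mask)
  cls <- maskLabels(cm)
  expect_identical(sum(cls != 0), sum(lab != 0))     # support equality
  expect_setequal(unique(cls[cls > 0]), c(1L, 2L))
  expect_true(all(cls[lab == 4L] == 1L))
  expect_true(all(cls[lab == 7L] == 2L))

  # all objects one class -> the binarized mask
  tab1 <- transform(tab, class = 1L)
  expect_identical(maskLabels(renderClassMask(pr$mask, tab1)),
                   array((lab > 0) + 0L, dim(lab)))

  expect_error(renderClassMask(pr$mask, tab[1, ]), "7")
})

test_that("countPerClass sums to the number of objects", {
  tab <- data.frame(image_id = "x", object_id = 1:7,
                    class = c(1L, 1L, 2L, 2L, 2L, 3L, 3L), confidence = 1)
  cnt <- countPerClass(tab)
  expect_identical(sum(cnt), 7L)
  expect_identical(unname(cnt[["2"]]), 3L)
  expect_length(countPerClass(tab[0, ]), 0L)
  expect_identical(names(countPerClass(transform(tab, class = 1L))), "1")
})

test_that("folder prediction matches per-image prediction and writes outputs", {
  td <- withr::local_tempdir()
  imgs <- file.path(td, "images"); msks <- file.path(td, "masks")
  out <- file.path(td, "out")
  dir.create(imgs); dir.create(msks)
  scenes <- lapply(1:3, function(s) genCells(nCells = 12, seed = s,
                                             canvas = c(96L, 96L)))
  for (s in 1:3) {
    writeImageVolume(sceneImage(scenes[[s]]),
                     file.path(imgs, sprintf("scene%d.tif", s)))
    writeLabelMask(sceneMask(scenes[[s]]),
                   file.path(msks, sprintf("scene%d.tif", s)))
  }
  m <- buildModel(classifierSpec(2, 2, 8, 2, 2, 3, 16), seed = 2,
                  patchSettings = list(includeMaskChannel = TRUE,
                                       normalization = "minmax"))
  summary <- predictFolder(m, imgs, msks, out)
  expect_identical(nrow(summary), 3L)
  expect_identical(sort(list.files(out, pattern = "classmask")),
                   sprintf("scene%d_classmask.tif", 1:3))
  expect_true(file.exists(file.path(out, "class_counts.csv")))

  # identical to per-image prediction on the same pair
  pr <- readPair(file.path(imgs, "scene2.tif"), file.path(msks, "scene2.tif"))
  solo <- predictObjects(m, pr$image, pr$mask)
  batch <- readPredictionTable(file.path(out, "scene2_predictions.csv"))
  expect_identical(batch$class, solo$class)
  expect_equal(batch$confidence, solo$confidence, tolerance = 1e-6)

  # unmatched stem aborts with a listing
  writeLabelMask(LabelMask(matrix(0L, 4, 4), "x"), file.path(msks, "x.tif"))
  expect_error(predictFolder(m, imgs, msks, out), "x")

  # empty folders exit cleanly with an empty summary
  e1 <- file.path(td, "e1"); e2 <- file.path(td, "e2")
  dir.create(e1); dir.create(e2)
  expect_identical(nrow(predictFolder(m, e1, e2, file.path(td, "eo"))), 0L)
})

test_that("3D volumes classify end-to-end: one row per segmented object", {
  sc <- genBlobs3d(nBlobs = 20, twoClassRule = "intensity", seed = 9)
  ann <- sampleTruthAnnotations(sc, 4, seed = 10)
  img <- new("ImageVolume", pixels = pixels(sceneImage(sc)) / 255,
             imageId = "blobs3d")
  ps <- buildPatchSet(img, sceneMask(sc), ann, 12, normalization = "none")
  spec <- classifierSpec(dim = 3, depth = 2, width = 8, inChannels = 2,
                         nClasses = 2, patchSize = 12)
  res <- trainClassifier(buildModel(spec, seed = 11,
                                    patchSettings = list(
                                      includeMaskChannel = TRUE,
                                      normalization = "none")),
                         ps, trainingConfig(epochs = 60, seed = 11))
  tab <- predictObjects(res$model, img, sceneMask(sc))
  expect_identical(nrow(tab), nObjects(sceneMask(sc)))
  acc <- predictionAccuracy(sceneTruth(sc), tab,
                            exclude = annotations(ann)$object_id)
  expect_gte(acc, 0.9)    # intensity gap is 20x the noise SD
})
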