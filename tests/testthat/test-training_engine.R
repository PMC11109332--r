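test_that("built-in augmentations satisfy their group identities", {
  p <- array(runif(2 * 6 * 6), c(2, 6, 6))
  hf <- function(x) augmentPatch(x, list(list(name = "hflip")))
  vf <- function(x) augmentPatch(x, list(list(name = "vflip")))
  r90 <- function(x) augmentPatch(x, list(list(name = "rot90")))
  expect_identical(hf(hf(p)), p)                 # involution
  expect_identical(vf(vf(p)), p)
  expect_identical(r90(r90(r90(r90(p)))), p)     # rot90^4 = identity
  expect_false(identical(r90(p), p))

  # probabilities of 0 make the pipeline the identity
  pipe0 <- list(list(name = "hflip", probability = 0),
                list(name = "rotate", probability = 0))
  expect_identical(augmentPatch(p, pipe0), p)

  # unknown transforms are rejected with the known names
  expect_error(augmentPatch(p, list(list(name = "zoom"))), "hflip")

  # mask channel transformed identically to intensity channels
  p2 <- p; p2[2, , ] <- (p2[1, , ] > 0.5) + 0
  out <- hf(p2)
  expect_identical(out[2, , ], (out[1, , ] > 0.5) + 0)

  # rotate keeps shape and is the identity for angle 0
  rot0 <- augmentPatch(p, list(list(name = "rotate",
                                    params = list(angle_range = c(0, 0)))))
  expect_identical(rot0, p)
  # 3D patches rotate in the (Y,X) plane
  p3 <- array(runif(1 * 4 * 6 * 6), c(1, 4, 6, 6))
  expect_identical(dim(augmentPatch(p3, list(list(name = "rot90")))),
                   dim(p3))
})

test_that("registered custom transforms participate in pipelines", {
  registerAugmentation("negate_test", function(patch, params, nd) -patch)
  p <- array(runif(8), c(2, 2, 2))
  expect_identical(augmentPatch(p, list(list(name = "negate_test"))), -p)
  expect_true("negate_test" %in% knownAugmentations())
})

test_that("makeSplits stratifies per class deterministically", {
  ps <- noisePatchSet(n = 20, K = 2, seed = 2)    # 10 + 10
  sp <- makeSplits(ps, 0.2, seed = 5)
  expect_identical(as.vector(table(patchLabels(sp$train))), c(8L, 8L))
  expect_identical(as.vector(table(patchLabels(sp$val))), c(2L, 2L))
  sp2 <- makeSplits(ps, 0.2, seed = 5)
  expect_identical(objectIds(sp$val), objectIds(sp2$val))

  expect_identical(nObjects(makeSplits(ps, 0, seed = 1)$val), 0L)
  # singleton classes always stay in train under the floor rule
  tiny <- noisePatchSet(n = 2, K = 2)
  expect_identical(nObjects(makeSplits(tiny, 0.5, seed = 1)$train), 2L)
  expect_error(makeSplits(ps, 0.6, seed = 1), "0.5")
})

test_that("epoch-1 loss of an untrained model is about ln K", {
  for (K in c(2L, 4L)) {
    ps <- noisePatchSet(n = 4L * K, K = K, seed = K)
    spec <- tinySpec2d(inChannels = 1, nClasses = K)
    res <- trainClassifier(buildModel(spec, seed = 1), ps,
                           trainingConfig(epochs = 1, batchSize = 64,
                                          learningRate = 1e-5, seed = 1))
    expect_lt(abs(res$history$loss[1] - log(K)) / log(K), 0.10)
  }
})

test_that("training declares empty classes and non-finite losses", {
  ps <- noisePatchSet(n = 6, K = 1, seed = 3)     # all labels class 1
  spec <- tinySpec2d(inChannels = 1, nClasses = 2)
  expect_error(trainClassifier(buildModel(spec, seed = 1), ps,
                               trainingConfig(epochs = 1, seed = 1)),
               "class\\(es\\) with 0 training examples: 2")
})

test_that("any model overfits 20 patches to 100% training accuracy", {
  set.seed(9)
  ps <- noisePatchSet(n = 20, C = 1, s = 16, K = 2, seed = 9)
  spec <- classifierSpec(2, 2, 16, 1, 2, 3, 16)
  res <- trainClassifier(buildModel(spec, seed = 4), ps,
                         trainingConfig(epochs = 600, seed = 4))  # default budget
  expect_identical(tail(res$history$accuracy, 1), 1)
})

test_that("training is bit-identical given config + seed", {
  td <- withr::local_tempdir()
  ps <- noisePatchSet(n = 10, K = 2, seed = 5)
  spec <- tinySpec2d(inChannels = 1)
  cfg <- trainingConfig(epochs = 5, seed = 42,
                        augmentation = list(list(name = "hflip",
                                                 probability = 0.5)))
  r1 <- trainClassifier(buildModel(spec, seed = 42), ps, cfg)
  r2 <- trainClassifier(buildModel(spec, seed = 42), ps, cfg)
  expect_identical(r1$history, r2$history)
  saveCheckpoint(r1$model, file.path(td, "a"))
  saveCheckpoint(r2$model, file.path(td, "b"))
  expect_identical(unname(tools::md5sum(file.path(td, "a.rds"))),
                   unname(tools::md5sum(file.path(td, "b.rds"))))
})

test_that("validation split reports a held-out accuracy", {
  sc <- genCells(nCells = 40, seed = 12, canvas = c(160L, 160L))
  img <- ImageVolume(pixels(sceneImage(sc)) / 255, "cells")
  ps <- buildPatchSet(img, sceneMask(sc), annotationsFromTruth(sc), 16,
                      normalization = "none")
  spec <- classifierSpec(2, 2, 8, 2, 2, 3, 16)
  res <- trainClassifier(buildModel(spec, seed = 2),
                         ps, trainingConfig(epochs = 40, seed = 2,
                                            validationFraction = 0.25))
  expect_false(is.na(res$valAccuracy))
  expect_gte(res$valAccuracy, 0.8)
  expect_identical(nrow(res$history), 40L)
})

test_that("inverse-frequency class weighting trains on imbalanced sets", {
  set.seed(3)
  n <- 12
  ps <- new("PatchSet",
            patches = array(runif(1 * 8 * 8 * n), c(1, 8, 8, n)),
            labels = c(rep(1L, 9), rep(2L, 3)),
            objectIds = seq_len(n), imageId = "imb",
            patchSize = c(8L, 8L))
  spec <- tinySpec2d(inChannels = 1)
  r1 <- trainClassifier(buildModel(spec, seed = 1), ps,
                        trainingConfig(epochs = 3, seed = 1),
                        classWeighting = "inverse_frequency")
  r2 <- trainClassifier(buildModel(spec, seed = 1), ps,
                        trainingConfig(epochs = 3, seed = 1),
                        classWeighting = "inverse_frequency")
  expect_identical(r1$history, r2$history)
  expect_true(all(is.finite(r1$history$loss)))
})
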