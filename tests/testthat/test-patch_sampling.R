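test_that("objectCentroids floors the mean coordinate per object", {
  m <- matrix(0L, 30, 30)
  m[10:12, 10:12] <- 1L                       # symmetric square -> (11,11)
  cents <- objectCentroids(LabelMask(m, "a"))
  expect_identical(cents[["1"]], c(11L, 11L))

  # exactly the declared ids, nothing else
  m2 <- matrix(0L, 10, 10)
  m2[2, 2] <- 3L; m2[8, 8] <- 9L
  expect_setequal(names(objectCentroids(LabelMask(m2, "a"))), c("3", "9"))

  # L-shape at (1,1),(1,2),(2,1): mean (4/3, 4/3) -> floor (1,1)
  m3 <- matrix(0L, 5, 5)
  m3[1, 1] <- 1L; m3[1, 2] <- 1L; m3[2, 1] <- 1L
  expect_identical(objectCentroids(LabelMask(m3, "a"))[["1"]], c(1L, 1L))

  # empty mask -> empty mapping, not an error
  expect_length(objectCentroids(LabelMask(matrix(0L, 4, 4), "a")), 0L)
})

test_that("extractPatch window arithmetic and zero padding", {
  img <- matrix(seq_len(100 * 100), 100, 100)   # distinct values everywhere
  msk <- matrix(0L, 100, 100)
  msk[50, 50] <- 1L                             # centroid (50,50)
  iv <- ImageVolume(img, "a"); lm <- LabelMask(msk, "a")
  p <- extractPatch(iv, lm, 1L, 45, includeMaskChannel = FALSE)
  expect_identical(dim(p), c(1L, 45L, 45L))
  expect_identical(p[1, , ], img[28:72, 28:72] + 0)   # rows/cols 28..72

  # centroid at the corner: 22-wide zero border on the low sides
  msk2 <- matrix(0L, 100, 100); msk2[1, 1] <- 1L
  p2 <- extractPatch(iv, LabelMask(msk2, "a"), 1L, 45,
                     includeMaskChannel = FALSE)
  expect_identical(dim(p2), c(1L, 45L, 45L))
  expect_true(all(p2[1, 1:22, ] == 0))
  expect_true(all(p2[1, , 1:22] == 0))
  expect_identical(p2[1, 23:45, 23:45], img[1:23, 1:23] + 0)
  # in-bounds voxels copied + padded voxels = the whole window
  expect_identical(23L * 23L + sum(p2[1, , ] == 0), 45L * 45L)

  # the mask channel holds only the target object's silhouette
  pr <- tinyPair()
  p3 <- extractPatch(pr$image, pr$mask, 7L, 9, includeMaskChannel = TRUE)
  expect_identical(dim(p3), c(2L, 9L, 9L))
  sub <- maskLabels(pr$mask)[7:15, 12:20]
  expect_identical(p3[2, , ] > 0, sub == 7L)

  expect_error(extractPatch(pr$image, pr$mask, 99L, 9), "99")
})

test_that("normalizePatch modes and degenerate cases", {
  p <- array(c(10, 12, 15, 20), c(1, 2, 2))
  out <- normalizePatch(p, "minmax")
  expect_equal(range(out), c(0, 1))
  expect_equal(out[1, , ], (p[1, , ] - 10) / 10)
  # idempotent after the affine map
  expect_equal(normalizePatch(out, "minmax"), out)
  # constant patch -> all zeros
  expect_identical(normalizePatch(array(7, c(1, 3, 3)), "minmax"),
                   array(0, c(1, 3, 3)))
  # none is the identity
  expect_identical(normalizePatch(p, "none"), p)
  # per-channel: each channel spans [0,1] on its own
  p2 <- array(0, c(2, 2, 2)); p2[1, , ] <- 1:4; p2[2, , ] <- 101:104
  out2 <- normalizePatch(p2, "per_channel_minmax")
  expect_equal(range(out2[1, , ]), c(0, 1))
  expect_equal(range(out2[2, , ]), c(0, 1))
})

test_that("buildPatchSet is order-stable, labeled and validated", {
  sc <- genCells(nCells = 26, seed = 4, canvas = c(128L, 128L))
  ps <- buildPatchSet(sceneImage(sc), sceneMask(sc), "all", 16)
  expect_identical(nObjects(ps), 26L)
  expect_identical(objectIds(ps), sort(objectIds(ps)))
  expect_null(patchLabels(ps))

  ann <- annotationsFromTruth(sc, ids = c(9L, 3L, 17L))
  ps2 <- buildPatchSet(sceneImage(sc), sceneMask(sc), ann, 16)
  expect_identical(objectIds(ps2), c(3L, 9L, 17L))   # ascending id order
  expect_identical(patchLabels(ps2),
                   unname(sceneTruth(sc)[c("3", "9", "17")]))

  # deterministic
  expect_identical(ps2@patches,
                   buildPatchSet(sceneImage(sc), sceneMask(sc), ann, 16)@patches)

  # annotation referencing an absent id lists the offenders
  bad <- AnnotationSet(data.frame(image_id = "cells", object_id = 999L,
                                  class = 1L))
  expect_error(buildPatchSet(sceneImage(sc), sceneMask(sc), bad, 16), "999")

  # empty annotation set -> empty PatchSet
  ps3 <- buildPatchSet(sceneImage(sc), sceneMask(sc), AnnotationSet(), 16)
  expect_identical(nObjects(ps3), 0L)
})

test_that("3D patches extract with correct geometry", {
  sc <- genBlobs3d(nBlobs = 6, seed = 3)
  ps <- buildPatchSet(sceneImage(sc), sceneMask(sc), "all", 12)
  expect_identical(dim(ps@patches), c(2L, 12L, 12L, 12L, 6L))
  # mask channel is binary and nonempty for each object
  for (i in 1:6) expect_gt(sum(ps@patches[2, , , , i]), 0)
})
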