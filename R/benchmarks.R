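#' @include cli.R
NULL

## Reference benchmark protocols for the two synthetic classification tasks.
## Each is a pure function of its seed: scene generation, label sampling,
## initialization and training all derive from it with fixed offsets.

benchSeeds <- function(seed) {
  seed <- as.integer(seed)
  list(scene = seed, labels = seed + 70001L, train = seed + 140002L)
}

#' Gray-level cell benchmark: 10 labels, held-out accuracy
#'
#' Generates a [genCells()] scene (120 disks, class means 80/180, noise SD
#' 5 - a 20x mean gap), samples 5 labels per class, trains the
#' depth-3/width-32 minimalist CNN on 16x16 patches and reports accuracy
#' on all remaining objects. Because the absolute gray level is the class
#' signal, patches are kept on a global [0,1] scale (white point 255)
#' rather than per-patch min-max, which would erase it.
#'
#' @param seed benchmark seed (drives everything).
#' @param epochs training epochs (default 200).
#' @param augmentation optional augmentation pipeline.
#' @param nPerClass labels per class (default 5).
#' @return list(accuracy, model, scene, labeledIds, table).
#' @export
benchmarkCells <- function(seed, epochs = 200, augmentation = list(),
                           nPerClass = 5) {
  sds <- benchSeeds(seed)
  scene <- genCells(seed = sds$scene)
  img <- ImageVolume(pixels(sceneImage(scene)) / 255,
                     imageId(sceneImage(scene)))
  ann <- sampleTruthAnnotations(scene, nPerClass, seed = sds$labels)
  pset <- buildPatchSet(img, sceneMask(scene), ann, 16,
                        normalization = "none")
  spec <- classifierSpec(dim = 2, depth = 3, width = 32, inChannels = 2,
                         nClasses = 2, patchSize = 16)
  model <- buildModel(spec, seed = sds$train,
                      patchSettings = list(includeMaskChannel = TRUE,
                                           normalization = "none"))
  res <- trainClassifier(model, pset,
                         trainingConfig(epochs = epochs, seed = sds$train,
                                        augmentation = augmentation))
  tab <- predictObjects(res$model, img, sceneMask(scene))
  labeled <- annotations(ann)$object_id
  list(accuracy = predictionAccuracy(sceneTruth(scene), tab,
                                     exclude = labeled),
       model = res$model, scene = scene, image = img,
       labeledIds = labeled, table = tab)
}

#' Oriented-texture benchmark: 45 labels, held-out accuracy
#'
#' Generates a [genOrientedTextures()] scene (156 tiles, orientations
#' 0/90 degrees, matched per-tile mean and variance), samples 45 tiles at
#' random as labels, trains the depth-3/width-32 minimalist CNN on 32x32
#' min-max-normalized patches with no augmentation (rotations would alias
#' the orientation classes by construction) and reports accuracy on the
#' remaining tiles.
#'
#' @param seed benchmark seed.
#' @param nLabels number of labeled tiles (default 45).
#' @param epochs training epochs (default 100).
#' @param layout tile class layout, passed to [genOrientedTextures()].
#' @return list(accuracy, model, scene, labeledIds, table).
#' @export
benchmarkTextures <- function(seed, nLabels = 45, epochs = 100,
                              layout = "random") {
  sds <- benchSeeds(seed)
  scene <- genOrientedTextures(seed = sds$scene, layout = layout)
  ids <- sort(sampleObjects(sceneMask(scene), nLabels, seed = sds$labels))
  ann <- annotationsFromTruth(scene, ids = ids)
  pset <- buildPatchSet(sceneImage(scene), sceneMask(scene), ann, 32,
                        normalization = "minmax")
  spec <- classifierSpec(dim = 2, depth = 3, width = 32, inChannels = 2,
                         nClasses = 2, patchSize = 32)
  model <- buildModel(spec, seed = sds$train)
  res <- trainClassifier(model, pset,
                         trainingConfig(epochs = epochs, seed = sds$train))
  tab <- predictObjects(res$model, sceneImage(scene), sceneMask(scene))
  list(accuracy = predictionAccuracy(sceneTruth(scene), tab, exclude = ids),
       model = res$model, scene = scene, labeledIds = ids, table = tab)
}

#' Random-forest baseline on the texture benchmark
#'
#' Same scene and labels as [benchmarkTextures()], but classifying with
#' the pre-defined-feature random forest. With matched per-tile moments no
#' radiometric or morphometric feature encodes the orientation, so the
#' forest cannot do much better than chance; with spatial features and a
#' segregated layout it can exploit position instead (a confound that
#' collapses under rotation).
#'
#' @param seed benchmark seed.
#' @param nLabels number of labeled tiles.
#' @param includeSpatial feed centroid coordinates to the forest.
#' @param layout tile class layout.
#' @return list(accuracy, accuracyRotated (NA unless includeSpatial),
#'   scene, labeledIds).
#' @export
benchmarkTexturesRF <- function(seed, nLabels = 45, includeSpatial = FALSE,
                                layout = "random") {
  sds <- benchSeeds(seed)
  scene <- genOrientedTextures(seed = sds$scene, layout = layout)
  ids <- sort(sampleObjects(sceneMask(scene), nLabels, seed = sds$labels))
  truth <- sceneTruth(scene)
  img <- sceneImage(scene)
  msk <- sceneMask(scene)
  feats <- rfBaselineFeatureTable(img, msk, includeSpatial = includeSpatial)
  allIds <- objectIds(msk)
  testIds <- setdiff(allIds, ids)
  pred <- rfBaselineTrainPredict(feats[as.character(ids), ],
                                 truth[as.character(ids)],
                                 feats[as.character(testIds), ],
                                 seed = sds$train)
  acc <- mean(pred == truth[as.character(testIds)])
  accRot <- NA_real_
  if (includeSpatial) {
    rot <- rotateScene90(scene)
    featsRot <- rfBaselineFeatureTable(sceneImage(rot), sceneMask(rot),
                                       includeSpatial = TRUE)
    predRot <- rfBaselineTrainPredict(feats[as.character(ids), ],
                                      truth[as.character(ids)],
                                      featsRot[as.character(testIds), ],
                                      seed = sds$train)
    accRot <- mean(predRot == truth[as.character(testIds)])
  }
  list(accuracy = acc, accuracyRotated = accRot, scene = scene,
       labeledIds = ids)
}
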