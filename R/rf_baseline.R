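#' @include evaluate.R
NULL

#' Pre-defined radiometric/morphometric features of one object
#'
#' The classic object-classification feature families: geometry of the
#' segmented region (area/volume, equivalent diameter) and intensity
#' statistics inside and just outside it (mean, variance, quantiles of the
#' interior; mean of a 2-voxel exterior ring, background only). Centroid
#' coordinates are appended iff \code{includeSpatial}, which makes the
#' classifier position-aware (and position is a classic confounding
#' variable: it can separate classes in the training image yet collapse
#' under rotation).
#'
#' @param image an [ImageVolume-class] (channel 1 is used).
#' @param mask the paired [LabelMask-class].
#' @param objectId id present in the mask.
#' @param includeSpatial append centroid coordinates (default FALSE).
#' @return named numeric feature vector.
#' @export
rfBaselineFeatures <- function(image, mask, objectId,
                               includeSpatial = FALSE) {
  lab <- maskLabels(mask)
  d <- dim(lab)
  nd <- length(d)
  w <- which(lab == objectId)
  if (length(w) == 0L) stop("object id ", objectId, " not present in mask")
  co <- arrayInd(w, d)
  px <- pixels(image)
  ## channel-1 intensities at the object's voxels
  chStride <- dim(px)[1L]
  inten <- px[1L + (w - 1L) * chStride]
  area <- length(w)
  eqd <- if (nd == 2L) 2 * sqrt(area / pi) else (6 * area / pi)^(1 / 3)
  q <- stats::quantile(inten, c(.10, .25, .50, .75, .90), names = FALSE)
  ## exterior ring: Chebyshev dilation by 2, background voxels only
  ringIdx <- dilateIndices(w, d, radius = 2L)
  ring <- ringIdx[lab[ringIdx] == 0L]
  ringMean <- if (length(ring) > 0) mean(px[1L + (ring - 1L) * chStride])
              else mean(inten)
  out <- c(area = area, eq_diameter = eqd,
           interior_mean = mean(inten),
           interior_var = if (area > 1) stats::var(inten) else 0,
           q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5],
           exterior_ring_mean = ringMean)
  if (includeSpatial) {
    ctr <- colMeans(co)
    names(ctr) <- paste0("centroid_", seq_len(nd))
    out <- c(out, ctr)
  }
  out
}

dilateIndices <- function(w, d, radius = 2L) {
  nd <- length(d)
  co <- arrayInd(w, d)
  offs <- as.matrix(expand.grid(rep(list(-radius:radius), nd)))
  out <- integer(0)
  strides <- cumprod(c(1L, d[-nd]))
  for (i in seq_len(nrow(offs))) {
    sh <- sweep(co, 2L, offs[i, ], "+")
    ok <- rep(TRUE, nrow(sh))
    for (a in seq_len(nd)) ok <- ok & sh[, a] >= 1L & sh[, a] <= d[a]
    out <- c(out, as.integer((sh[ok, , drop = FALSE] - 1) %*% strides + 1))
  }
  setdiff(unique(out), w)
}

#' Feature table for many objects
#'
#' @param image,mask as in [rfBaselineFeatures()].
#' @param ids object ids (default all).
#' @param includeSpatial append centroid coordinates.
#' @return data.frame, one row per id (row names = ids).
#' @export
rfBaselineFeatureTable <- function(image, mask, ids = NULL,
                                   includeSpatial = FALSE) {
  if (is.null(ids)) ids <- objectIds(mask)
  rows <- lapply(ids, function(id)
    rfBaselineFeatures(image, mask, id, includeSpatial = includeSpatial))
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- ids
  out
}

#' Random-forest baseline: fit on labeled features, predict test features
#'
#' A bagged ensemble of decision trees over the pre-defined features with
#' majority voting (100 trees by default, seeded). This is the
#' fixed-feature counterpart of the CNN: strong whenever a pre-defined
#' feature is discriminant, and structurally blind to properties (such as
#' texture orientation) that no pre-defined feature encodes.
#'
#' @param trainFeatures data.frame/matrix of features.
#' @param trainLabels integer classes (>= 1 example per class).
#' @param testFeatures data.frame/matrix with the same columns.
#' @param nTrees number of trees (default 100).
#' @param seed RNG seed.
#' @return integer vector of predicted classes for the test rows.
#' @export
rfBaselineTrainPredict <- function(trainFeatures, trainLabels, testFeatures,
                                   nTrees = 100L, seed = 0) {
  labs <- factor(trainLabels)
  if (nlevels(labs) < 2L)
    stop("random-forest baseline needs >= 2 classes in training labels")
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = as.data.frame(trainFeatures),
                                    y = labs, ntree = nTrees)
  as.integer(as.character(stats::predict(fit,
                                         as.data.frame(testFeatures))))
}
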