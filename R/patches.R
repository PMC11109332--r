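#' @include synthetic.R
NULL

#' Object centroids of a label mask
#'
#' One entry per distinct nonzero id; the center is the floor of the mean
#' voxel coordinate (0-based per axis would floor identically; coordinates
#' here are 1-based R indices, floored after averaging).
#'
#' @param mask a [LabelMask-class].
#' @return named list: object id -> integer coordinate vector (one per
#'   spatial axis). An empty mask gives an empty list.
#' @export
objectCentroids <- function(mask) {
  lab <- maskLabels(mask)
  ids <- objectIds(mask)
  if (length(ids) == 0L) return(structure(list(), names = character()))
  w <- which(lab > 0)
  co <- arrayInd(w, dim(lab))
  v <- lab[w]
  out <- lapply(ids, function(id) {
    as.integer(floor(colMeans(co[v == id, , drop = FALSE])))
  })
  names(out) <- ids
  out
}

#' Extract a fixed-size patch centered on one object
#'
#' The crop window spans \code{center - floor(s/2) .. center - floor(s/2)
#' + s - 1} on each axis; out-of-bounds voxels are zero-filled, so border
#' objects yield full-size patches. With \code{includeMaskChannel}, an
#' extra trailing channel holds the binary silhouette of \code{objectId}
#' only (other objects in the window are zeroed), which disambiguates
#' which object the classifier is being asked about.
#'
#' @param image an [ImageVolume-class].
#' @param mask the paired [LabelMask-class].
#' @param objectId id present in the mask.
#' @param patchSize integer spatial extents (scalar recycled).
#' @param includeMaskChannel logical (default TRUE).
#' @param centroids optional precomputed [objectCentroids()] list.
#' @return numeric array (C', spatial...).
#' @export
extractPatch <- function(image, mask, objectId, patchSize,
                         includeMaskChannel = TRUE, centroids = NULL) {
  lab <- maskLabels(mask)
  sd <- dim(lab)
  nd <- length(sd)
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, nd)
  patchSize <- as.integer(patchSize)
  if (is.null(centroids)) {
    w <- which(lab == objectId)
    if (length(w) == 0L) stop("object id ", objectId, " not present in mask")
    ctr <- as.integer(floor(colMeans(arrayInd(w, sd))))
  } else {
    ctr <- centroids[[as.character(objectId)]]
    if (is.null(ctr)) stop("object id ", objectId, " not present in mask")
  }
  px <- pixels(image)
  C <- dim(px)[1L]
  lo <- ctr - patchSize %/% 2L
  hi <- lo + patchSize - 1L
  srcLo <- pmax(lo, 1L)
  srcHi <- pmin(hi, sd)
  dstLo <- srcLo - lo + 1L
  dstHi <- dstLo + (srcHi - srcLo)
  Cout <- C + as.integer(includeMaskChannel)
  patch <- array(0, c(Cout, patchSize))
  srcIdx <- lapply(seq_len(nd), function(a) srcLo[a]:srcHi[a])
  dstIdx <- lapply(seq_len(nd), function(a) dstLo[a]:dstHi[a])
  patch <- do.call(`[<-`, c(list(patch), list(seq_len(C)), dstIdx,
    list(value = do.call(`[`, c(list(px), list(seq_len(C)), srcIdx,
                                list(drop = FALSE))))))
  if (includeMaskChannel) {
    sub <- do.call(`[`, c(list(lab), srcIdx, list(drop = FALSE)))
    bin <- array(as.numeric(sub == objectId), dim(sub))
    patch <- do.call(`[<-`, c(list(patch), list(Cout), dstIdx,
      list(value = array(bin, c(1L, dim(bin))))))
  }
  patch
}

#' Normalize a patch
#'
#' \code{minmax} rescales the whole patch affinely to [0, 1] by its own
#' minimum and maximum; \code{per_channel_minmax} does the same per
#' channel; \code{none} is the identity. A constant patch (max == min)
#' maps to all zeros.
#'
#' @param patch numeric array (C', spatial...).
#' @param mode one of "minmax", "per_channel_minmax", "none".
#' @return the normalized array (same shape).
#' @export
normalizePatch <- function(patch,
                           mode = c("minmax", "per_channel_minmax", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(patch)
  mm <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) array(0, dim(x)) else (x - lo) / (hi - lo)
  }
  if (mode == "minmax") {
    out <- mm(patch)
  } else {
    out <- patch
    d <- dim(patch)
    for (ch in seq_len(d[1L])) {
      idx <- c(list(ch), rep(list(quote(expr = )), length(d) - 1L))
      sl <- do.call(`[`, c(list(patch), idx, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idx, list(value = mm(sl))))
    }
  }
  out
}

#' Build a PatchSet for annotated objects (or all objects)
#'
#' One patch per requested object, in ascending object-id order, with
#' labels attached when an annotation set is given.
#'
#' @param image an [ImageVolume-class].
#' @param mask the paired [LabelMask-class].
#' @param which an [AnnotationSet-class] (records for this image's id are
#'   used and provide labels) or the string \code{"all"} for every object,
#'   unlabeled.
#' @param patchSize integer spatial extents (scalar recycled).
#' @param includeMaskChannel logical (default TRUE).
#' @param normalization normalization mode applied per patch (see
#'   [normalizePatch()]; default "minmax").
#' @return a [PatchSet-class].
#' @export
buildPatchSet <- function(image, mask, which = "all", patchSize,
                          includeMaskChannel = TRUE,
                          normalization = "minmax") {
  nd <- length(dim(maskLabels(mask)))
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, nd)
  patchSize <- as.integer(patchSize)
  present <- objectIds(mask)
  if (identical(which, "all")) {
    ids <- present
    labels <- NULL
  } else if (is(which, "AnnotationSet")) {
    rec <- annotations(which)
    rec <- rec[rec$image_id == imageId(mask), , drop = FALSE]
    missing <- setdiff(rec$object_id, present)
    if (length(missing) > 0)
      stop("annotation(s) reference absent object id(s): ",
           paste(sort(missing), collapse = ", "))
    o <- order(rec$object_id)
    ids <- as.integer(rec$object_id[o])
    labels <- as.integer(rec$class[o])
  } else {
    stop("'which' must be an AnnotationSet or \"all\"")
  }
  C <- nChannels(image) + as.integer(includeMaskChannel)
  n <- length(ids)
  patches <- array(0, c(C, patchSize, n))
  cents <- objectCentroids(mask)
  for (i in seq_len(n)) {
    p <- extractPatch(image, mask, ids[i], patchSize,
                      includeMaskChannel = includeMaskChannel,
                      centroids = cents)
    p <- normalizePatch(p, normalization)
    idx <- c(rep(list(quote(expr = )), nd + 1L), list(i))
    patches <- do.call(`[<-`, c(list(patches), idx, list(value = p)))
  }
  new("PatchSet", patches = patches, labels = labels,
      objectIds = ids, imageId = imageId(mask), patchSize = patchSize)
}

#' Subset a PatchSet by position
#'
#' @param x a [PatchSet-class].
#' @param i integer or logical index over patches.
#' @return the subset [PatchSet-class].
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  nd <- length(x@patchSize)
  idx <- c(rep(list(quote(expr = )), nd + 1L), list(i))
  patches <- do.call(`[`, c(list(x@patches), idx, list(drop = FALSE)))
  new("PatchSet", patches = patches,
      labels = if (is.null(x@labels)) NULL else x@labels[i],
      objectIds = x@objectIds[i], imageId = x@imageId,
      patchSize = x@patchSize)
})
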