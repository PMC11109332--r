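#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's data classes; user code should
#' use these rather than reaching into slots.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ImageVolume", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setMethod("maskLabels", "LabelMask", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("maskLabels", "ClassMask", function(x) x@classes)

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setMethod("imageId", "ImageVolume", function(x) x@imageId)
#' @rdname accessors
#' @export
setMethod("imageId", "LabelMask", function(x) x@imageId)
#' @rdname accessors
#' @export
setMethod("imageId", "PatchSet", function(x) x@imageId)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "ImageVolume", function(x) dim(x@pixels)[1L])

#' @rdname accessors
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))
#' @rdname accessors
#' @export
setMethod("spatialDim", "ImageVolume", function(x) dim(x@pixels)[-1L])
#' @rdname accessors
#' @export
setMethod("spatialDim", "LabelMask", function(x) dim(x@labels))

#' @rdname accessors
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))
#' @rdname accessors
#' @export
setMethod("objectIds", "LabelMask", function(x) {
  v <- sort(unique(as.vector(x@labels)))
  as.integer(v[v > 0])
})
#' @rdname accessors
#' @export
setMethod("objectIds", "PatchSet", function(x) x@objectIds)

#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setMethod("nObjects", "LabelMask", function(x) length(objectIds(x)))
#' @rdname accessors
#' @export
setMethod("nObjects", "PatchSet", function(x) length(x@objectIds))

#' @rdname accessors
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)
#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setMethod("sceneImage", "SyntheticScene", function(x) x@image)
#' @rdname accessors
#' @export
setGeneric("sceneMask", function(x) standardGeneric("sceneMask"))
#' @rdname accessors
#' @export
setMethod("sceneMask", "SyntheticScene", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))
#' @rdname accessors
#' @export
setMethod("modelSpec", "MinimalistCNN", function(x) x@spec)

#' @rdname accessors
#' @export
setGeneric("perClassCounts", function(x) standardGeneric("perClassCounts"))
#' @rdname accessors
#' @export
setMethod("perClassCounts", "MetricsReport", function(x) x@perClass)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageVolume '%s': %s (C=%d, %s)\n", object@imageId,
              if (length(d) == 3L) "2D" else "3D", d[1],
              paste(d[-1], collapse = "x")))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask '%s': %s, %d objects\n", object@imageId,
              paste(dim(object@labels), collapse = "x"), nObjects(object)))
})

setMethod("show", "AnnotationSet", function(object) {
  r <- object@records
  cat(sprintf("AnnotationSet: %d records over %d image(s)\n",
              nrow(r), length(unique(r$image_id))))
  if (nrow(r) > 0) {
    tb <- table(r$class)
    cat("  per class:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet '%s': n=%d, patch %s, %s\n", object@imageId,
              nObjects(object), paste(object@patchSize, collapse = "x"),
              if (is.null(object@labels)) "unlabeled" else "labeled"))
})

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf(
    "ClassifierSpec: %dD, depth %d, width %d, C=%d, K=%d, kernel %d, patch %s\n",
    object@dim, object@depth, object@width, object@inChannels,
    object@nClasses, object@kernelExtent,
    paste(object@patchSize, collapse = "x")))
})

setMethod("show", "MinimalistCNN", function(object) {
  show(object@spec)
  cat(sprintf("  %d trainable parameters\n", countParameters(object@spec)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:\n  ")
  show(object@image)
  cat("  ")
  show(object@mask)
  cat(sprintf("  %d classes\n", max(object@truth)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d classes\n", object@nClasses))
  cat("  as-printed: ",
      paste(sprintf("%s=%.4f", names(object@asPrinted), object@asPrinted),
            collapse = "  "), "\n")
  cat("  weighted:   ",
      paste(sprintf("%s=%.4f", names(object@weighted), object@weighted),
            collapse = "  "), "\n")
})
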