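#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' ImageVolume: a channel-first intensity image
#'
#' Holds a 2D or 3D intensity image with an explicit channel axis in first
#' position: \code{(C, Y, X)} for 2D, \code{(C, Z, Y, X)} for 3D. Values are
#' arbitrary finite numerics (conventionally on a 0..255 gray scale; patch
#' normalization makes the scale irrelevant downstream).
#'
#' @slot pixels numeric array, dim \code{(C, Y, X)} or \code{(C, Z, Y, X)}.
#' @slot imageId character scalar, typically the filename stem.
#' @export
setClass("ImageVolume",
  representation(pixels = "array", imageId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (is.null(d) || !(length(d) %in% c(3L, 4L)))
      return("pixels must be a 3D (C,Y,X) or 4D (C,Z,Y,X) array")
    if (d[1] < 1L || any(d[-1] < 1L))
      return("need C >= 1 and all spatial extents >= 1")
    if (!all(is.finite(object@pixels)))
      return("pixels must be finite")
    if (length(object@imageId) != 1L)
      return("imageId must be a single string")
    TRUE
  })

#' LabelMask: an integer instance segmentation mask
#'
#' Integer array over the spatial axes of its paired [ImageVolume-class]
#' (no channel axis): \code{(Y, X)} or \code{(Z, Y, X)}. 0 is background;
#' each positive value is one object id. Ids need not be contiguous.
#'
#' @slot labels integer array.
#' @slot imageId character scalar.
#' @export
setClass("LabelMask",
  representation(labels = "array", imageId = "character"),
  validity = function(object) {
    d <- dim(object@labels)
    if (is.null(d) || !(length(d) %in% c(2L, 3L)))
      return("labels must be a 2D (Y,X) or 3D (Z,Y,X) array")
    v <- object@labels
    if (!is.numeric(v) || any(v != floor(v)))
      return("labels must be integer-valued")
    if (min(v) < 0)
      return("labels must be >= 0 (0 = background)")
    if (length(object@imageId) != 1L)
      return("imageId must be a single string")
    TRUE
  })

#' ClassMask: per-voxel predicted class ids
#'
#' Same spatial geometry as the [LabelMask-class] it was rendered from;
#' every voxel of an object carries the object's predicted class (1..9),
#' background stays 0.
#'
#' @slot classes integer array.
#' @slot imageId character scalar.
#' @export
setClass("ClassMask",
  representation(classes = "array", imageId = "character"),
  validity = function(object) {
    v <- object@classes
    if (is.null(dim(v)) || !(length(dim(v)) %in% c(2L, 3L)))
      return("classes must be a 2D or 3D array")
    if (any(v != floor(v)) || min(v) < 0 || max(v) > 9)
      return("class values must be integers in 0..9")
    TRUE
  })

#' AnnotationSet: sparse per-object class labels
#'
#' The training supervision: at most one record per (image_id, object_id)
#' pair, classes restricted to 1..9 (the maximum number of classes), with a
#' provenance tag recording whether a label was entered manually, corrected
#' from a prediction, or confirmed from a prediction.
#'
#' @slot records data.frame with columns image_id (character),
#'   object_id (integer), class (integer 1..9), provenance (character,
#'   one of "manual", "corrected", "confirmed").
#' @export
setClass("AnnotationSet",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("image_id", "object_id", "class", "provenance")
    if (!all(need %in% names(r)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(r) == 0L) return(TRUE)
    if (any(r$class < 1L | r$class > 9L))
      return("classes must be in 1..9")
    if (!all(r$provenance %in% c("manual", "corrected", "confirmed")))
      return("provenance must be manual/corrected/confirmed")
    if (anyDuplicated(paste(r$image_id, r$object_id, sep = "\r")))
      return("duplicate (image_id, object_id) records")
    TRUE
  })

#' SyntheticScene: a generated benchmark scene with ground truth
#'
#' @slot image [ImageVolume-class].
#' @slot mask [LabelMask-class].
#' @slot truth named integer vector: names are object ids, values classes 1..K.
#' @slot params list of the generator parameters used (including the seed).
#' @export
setClass("SyntheticScene",
  representation(image = "ImageVolume", mask = "LabelMask",
                 truth = "integer", params = "list"),
  validity = function(object) {
    ids <- sort(unique(as.vector(object@mask@labels)))
    ids <- ids[ids > 0]
    tn <- as.integer(names(object@truth))
    if (!setequal(ids, tn))
      return("every object id in the mask must appear in truth (and vice versa)")
    k <- max(object@truth)
    if (!setequal(sort(unique(object@truth)), seq_len(k)))
      return("truth classes must cover 1..K")
    TRUE
  })

#' ClassifierSpec: architecture of a minimalist CNN
#'
#' The network family is parameterized only by its depth (number of
#' conv-ReLU-maxpool blocks) and width (filters per convolution), for 2D or
#' 3D patches with any number of input channels.
#'
#' @slot dim integer, 2 or 3.
#' @slot depth integer >= 1, number of conv blocks.
#' @slot width integer >= 1, filters per convolution.
#' @slot inChannels integer >= 1 (image channels, +1 if a mask channel is fed).
#' @slot nClasses integer in 2..9.
#' @slot kernelExtent odd integer, convolution kernel size per axis (default 3).
#' @slot patchSize integer vector, one extent per spatial axis.
#' @export
setClass("ClassifierSpec",
  representation(dim = "integer", depth = "integer", width = "integer",
                 inChannels = "integer", nClasses = "integer",
                 kernelExtent = "integer", patchSize = "integer"),
  validity = function(object) {
    if (!(object@dim %in% c(2L, 3L))) return("dim must be 2 or 3")
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@width < 1L) return("width must be >= 1")
    if (object@inChannels < 1L) return("inChannels must be >= 1")
    if (object@nClasses < 2L || object@nClasses > 9L)
      return("nClasses must be in 2..9")
    if (object@kernelExtent < 1L || object@kernelExtent %% 2L == 0L)
      return("kernelExtent must be a positive odd integer")
    if (length(object@patchSize) != object@dim)
      return("patchSize must have one extent per spatial axis")
    if (any(object@patchSize < 2L^object@depth))
      return(sprintf("patch too small for depth %d: every axis must be >= %d",
                     object@depth, 2L^object@depth))
    TRUE
  })

#' TrainingConfig: optimization settings
#'
#' @slot epochs integer >= 1.
#' @slot batchSize integer >= 1.
#' @slot learningRate positive numeric (Adam).
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot stepEvery integer, epochs between learning-rate decays.
#' @slot stepFactor numeric in (0, 1], multiplicative decay.
#' @slot loss character, currently "cross_entropy".
#' @slot augmentation list of list(name, params, probability), applied in order.
#' @slot validationFraction numeric in [0, 0.5].
#' @slot seed integer.
#' @export
setClass("TrainingConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
                 stepEvery = "integer", stepFactor = "numeric",
                 loss = "character", augmentation = "list",
                 validationFraction = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@stepFactor <= 0 || object@stepFactor > 1)
      return("stepFactor must be in (0, 1]")
    if (object@stepEvery < 1L) return("stepEvery must be >= 1")
    if (object@loss != "cross_entropy")
      return("only cross_entropy loss is supported")
    if (object@validationFraction < 0 || object@validationFraction > 0.5)
      return("validationFraction must be in [0, 0.5]")
    for (a in object@augmentation) {
      if (is.null(a$name)) return("each augmentation needs a name")
      p <- if (is.null(a$probability)) 1 else a$probability
      if (p < 0 || p > 1) return("augmentation probabilities must be in [0,1]")
    }
    TRUE
  })

#' PatchSet: fixed-size per-object patch tensors
#'
#' The tensor interface between sampling and learning: one fixed-size crop
#' per object, stored channel-first with the sample axis last, i.e.
#' \code{(C', Y, X, n)} in 2D or \code{(C', Z, Y, X, n)} in 3D (column-major
#' friendly). \code{C'} includes the optional binary mask channel.
#'
#' @slot patches numeric array as above.
#' @slot labels integer vector of classes 1..9, or NULL when unlabeled.
#' @slot objectIds integer vector of n object ids (unique within the image).
#' @slot imageId character scalar.
#' @slot patchSize integer vector of spatial extents.
#' @export
setClass("PatchSet",
  representation(patches = "array", labels = "integerOrNULL",
                 objectIds = "integer", imageId = "character",
                 patchSize = "integer"),
  validity = function(object) {
    d <- dim(object@patches)
    nd <- length(object@patchSize)
    if (length(d) != nd + 2L)
      return("patches must have dims (C', spatial..., n)")
    if (!all(d[2:(nd + 1L)] == object@patchSize))
      return("patch spatial dims must equal patchSize")
    n <- d[length(d)]
    if (length(object@objectIds) != n)
      return("objectIds length must equal the number of patches")
    if (anyDuplicated(object@objectIds))
      return("objectIds must be unique within an image")
    if (!is.null(object@labels)) {
      if (length(object@labels) != n)
        return("labels length must equal the number of patches")
      if (n > 0 && any(object@labels < 1L | object@labels > 9L))
        return("labels must be in 1..9")
    }
    TRUE
  })

#' MinimalistCNN: a built (possibly trained) classifier
#'
#' @slot spec [ClassifierSpec-class].
#' @slot weights list: per block \code{conv[[l]]$W} (width x fanin matrix) and
#'   \code{$b}; head \code{V} (K x width) and \code{c} (K).
#' @slot patchSettings list(includeMaskChannel, normalization) recorded so
#'   prediction normalizes patches exactly as at training time.
#' @export
setClass("MinimalistCNN",
  representation(spec = "ClassifierSpec", weights = "list",
                 patchSettings = "list"))

#' ExperimentConfig: the complete serializable experiment description
#'
#' Round-trips losslessly through JSON; every field has a default, so an
#' empty configuration file is valid.
#'
#' @slot classifier [ClassifierSpec-class].
#' @slot training [TrainingConfig-class].
#' @slot patch list(size, includeMaskChannel, normalization).
#' @slot paths list(inputDir, outputDir).
#' @slot seed integer master seed.
#' @export
setClass("ExperimentConfig",
  representation(classifier = "ClassifierSpec", training = "TrainingConfig",
                 patch = "list", paths = "list", seed = "integer"))

#' MetricsReport: per-class confusion counts and aggregate metrics
#'
#' Aggregates come in two flavors: the as-printed forms (with the class-size
#' weighting inside the per-class precision/recall fractions and the
#' macro-averaged accuracy) and the conventional support-weighted forms.
#'
#' @slot perClass data.frame with columns class, n, TP, FP, FN, TN.
#' @slot asPrinted named numeric: precision, recall, f1, accuracy.
#' @slot weighted named numeric: precision, recall, f1 (support-weighted)
#'   and accuracy (plain fraction correct).
#' @slot nClasses integer.
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", asPrinted = "numeric",
                 weighted = "numeric", nClasses = "integer"))

#' Heatmap: a Grad-CAM class activation map
#'
#' @slot raw non-negative array, spatial shape of the input patch.
#' @slot rescaled the same map min-max rescaled to [0,1] (zero map stays zero).
#' @slot targetClass integer.
#' @export
setClass("Heatmap",
  representation(raw = "array", rescaled = "array", targetClass = "integer"),
  validity = function(object) {
    if (min(object@raw) < 0) return("heatmap values must be >= 0")
    TRUE
  })
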