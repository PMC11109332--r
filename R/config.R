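#' @include io_images.R
NULL

#' Construct a ClassifierSpec
#'
#' @param dim 2 or 3.
#' @param depth number of conv-ReLU-maxpool blocks (>= 1).
#' @param width filters per convolution (>= 1). A width of 32 and depth of 3
#'   is the recommended default compromise.
#' @param inChannels input channels seen by the network (image channels plus
#'   one if the binary mask channel is fed).
#' @param nClasses number of classes, 2..9.
#' @param kernelExtent odd kernel size per axis (default 3).
#' @param patchSize spatial extents; scalar is recycled per axis. Defaults:
#'   137x137 in 2D, 45x45x45 in 3D.
#' @return a [ClassifierSpec-class].
#' @export
classifierSpec <- function(dim = 2, depth = 3, width = 32, inChannels = 1,
                           nClasses = 2, kernelExtent = 3, patchSize = NULL) {
  dim <- as.integer(dim)
  if (is.null(patchSize))
    patchSize <- if (identical(dim, 2L)) c(137L, 137L) else c(45L, 45L, 45L)
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, dim)
  new("ClassifierSpec", dim = dim, depth = as.integer(depth),
      width = as.integer(width), inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), kernelExtent = as.integer(kernelExtent),
      patchSize = as.integer(patchSize))
}

#' Construct a TrainingConfig
#'
#' Adam with step decay; defaults are common stable settings (lr 1e-3,
#' betas 0.9/0.999), 600 epochs, batch 16, decay factor 0.5 applied every
#' \code{ceiling(epochs/3)} epochs unless overridden.
#'
#' @param epochs,batchSize,learningRate,beta1,beta2 optimizer settings.
#' @param stepEvery epochs between learning-rate decays (default
#'   \code{ceiling(epochs/3)}).
#' @param stepFactor multiplicative decay in (0, 1].
#' @param loss currently only "cross_entropy".
#' @param augmentation ordered list of \code{list(name=, params=, probability=)}.
#' @param validationFraction stratified validation split fraction in [0, 0.5].
#' @param seed RNG seed governing init, shuffling and augmentation draws.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(epochs = 600, batchSize = 16, learningRate = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, stepEvery = NULL,
                           stepFactor = 0.5, loss = "cross_entropy",
                           augmentation = list(), validationFraction = 0,
                           seed = 0) {
  if (is.null(stepEvery)) stepEvery <- ceiling(epochs / 3)
  augmentation <- lapply(augmentation, canonicalAugmentation)
  new("TrainingConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      stepEvery = as.integer(stepEvery),
      stepFactor = as.numeric(stepFactor), loss = loss,
      augmentation = augmentation,
      validationFraction = as.numeric(validationFraction),
      seed = as.integer(seed))
}

canonicalAugmentation <- function(a) {
  if (is.null(a$name)) stop("each augmentation entry needs a 'name'")
  extra <- setdiff(names(a), c("name", "params", "probability"))
  if (length(extra) > 0)
    stop("unknown augmentation key(s): ", paste(extra, collapse = ", "))
  list(name = a$name,
       params = if (is.null(a$params)) structure(list(), names = character())
                else a$params,
       probability = if (is.null(a$probability)) 1 else a$probability)
}

#' Construct an ExperimentConfig
#'
#' @param classifier a [ClassifierSpec-class].
#' @param training a [TrainingConfig-class].
#' @param patch list(size, includeMaskChannel, normalization). \code{size}
#'   defaults to the classifier patch size; normalization is one of
#'   "minmax", "per_channel_minmax", "none".
#' @param paths list(inputDir, outputDir).
#' @param seed master seed for the run.
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(classifier = classifierSpec(),
                             training = trainingConfig(),
                             patch = list(), paths = list(), seed = 0) {
  pdef <- list(size = classifier@patchSize, includeMaskChannel = TRUE,
               normalization = "minmax")
  extra <- setdiff(names(patch), names(pdef))
  if (length(extra) > 0)
    stop("unknown patch key(s): ", paste(extra, collapse = ", "))
  pdef[names(patch)] <- patch
  pdef$size <- as.integer(pdef$size)
  if (length(pdef$size) == 1L) pdef$size <- rep(pdef$size, classifier@dim)
  if (!pdef$normalization %in% c("minmax", "per_channel_minmax", "none"))
    stop("normalization must be minmax, per_channel_minmax or none")
  ddef <- list(inputDir = ".", outputDir = ".")
  extra <- setdiff(names(paths), names(ddef))
  if (length(extra) > 0)
    stop("unknown paths key(s): ", paste(extra, collapse = ", "))
  ddef[names(paths)] <- paths
  new("ExperimentConfig", classifier = classifier, training = training,
      patch = pdef, paths = ddef, seed = as.integer(seed))
}

configAsList <- function(config) {
  cl <- config@classifier
  tr <- config@training
  list(
    seed = config@seed,
    classifier = list(dim = cl@dim, depth = cl@depth, width = cl@width,
                      in_channels = cl@inChannels, n_classes = cl@nClasses,
                      kernel_extent = cl@kernelExtent),
    patch = list(size = config@patch$size,
                 include_mask_channel = config@patch$includeMaskChannel,
                 normalization = config@patch$normalization),
    training = list(epochs = tr@epochs, batch_size = tr@batchSize,
                    learning_rate = tr@learningRate, beta1 = tr@beta1,
                    beta2 = tr@beta2,
                    step_decay = list(every_n_epochs = tr@stepEvery,
                                      factor = tr@stepFactor),
                    loss = tr@loss, augmentation = tr@augmentation,
                    validation_fraction = tr@validationFraction,
                    seed = tr@seed),
    paths = list(input_dir = config@paths$inputDir,
                 output_dir = config@paths$outputDir))
}

#' Save an ExperimentConfig as JSON
#'
#' @param config an [ExperimentConfig-class].
#' @param path output JSON file.
#' @return invisibly, \code{path}.
#' @export
saveConfig <- function(config, path) {
  lst <- configAsList(config)
  # keep the patch size an array even when scalar-like
  lst$patch$size <- I(lst$patch$size)
  for (i in seq_along(lst$training$augmentation)) {
    p <- lst$training$augmentation[[i]]$params
    lst$training$augmentation[[i]]$params <-
      lapply(p, function(v) if (length(v) > 1L) I(v) else v)
  }
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

checkKnownKeys <- function(given, known, where) {
  extra <- setdiff(names(given), known)
  if (length(extra) > 0)
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
}

#' Load an ExperimentConfig from JSON
#'
#' Missing keys are filled with the documented defaults (an empty object is
#' a complete default configuration); unknown keys are rejected by name;
#' invalid values fail naming the offending field.
#'
#' @param path JSON file.
#' @return an [ExperimentConfig-class].
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (length(raw) == 0L) raw <- structure(list(), names = character())
  configFromList(raw)
}

configFromList <- function(raw) {
  checkKnownKeys(raw, c("seed", "classifier", "patch", "training", "paths"),
                 "top level")
  cl <- raw$classifier
  checkKnownKeys(cl, c("dim", "depth", "width", "in_channels", "n_classes",
                       "kernel_extent"), "classifier")
  tr <- raw$training
  checkKnownKeys(tr, c("epochs", "batch_size", "learning_rate", "beta1",
                       "beta2", "step_decay", "loss", "augmentation",
                       "validation_fraction", "seed"), "training")
  if (!is.null(tr$step_decay))
    checkKnownKeys(tr$step_decay, c("every_n_epochs", "factor"),
                   "training$step_decay")
  pt <- raw$patch
  checkKnownKeys(pt, c("size", "include_mask_channel", "normalization"),
                 "patch")
  ph <- raw$paths
  checkKnownKeys(ph, c("input_dir", "output_dir"), "paths")

  pick <- function(x, default) if (is.null(x)) default else x
  dim <- as.integer(pick(cl$dim, 2L))
  defaultPatch <- if (dim == 2L) c(137L, 137L) else c(45L, 45L, 45L)
  size <- as.integer(pick(pt$size, defaultPatch))
  spec <- classifierSpec(
    dim = dim, depth = pick(cl$depth, 3L), width = pick(cl$width, 32L),
    inChannels = pick(cl$in_channels, 1L), nClasses = pick(cl$n_classes, 2L),
    kernelExtent = pick(cl$kernel_extent, 3L), patchSize = size)
  epochs <- as.integer(pick(tr$epochs, 600L))
  tcfg <- trainingConfig(
    epochs = epochs, batchSize = pick(tr$batch_size, 16L),
    learningRate = pick(tr$learning_rate, 1e-3),
    beta1 = pick(tr$beta1, 0.9), beta2 = pick(tr$beta2, 0.999),
    stepEvery = pick(tr$step_decay$every_n_epochs, ceiling(epochs / 3)),
    stepFactor = pick(tr$step_decay$factor, 0.5),
    loss = pick(tr$loss, "cross_entropy"),
    augmentation = pick(tr$augmentation, list()),
    validationFraction = pick(tr$validation_fraction, 0),
    seed = pick(tr$seed, 0L))
  experimentConfig(
    classifier = spec, training = tcfg,
    patch = list(size = size,
                 includeMaskChannel = pick(pt$include_mask_channel, TRUE),
                 normalization = pick(pt$normalization, "minmax")),
    paths = list(inputDir = pick(ph$input_dir, "."),
                 outputDir = pick(ph$output_dir, ".")),
    seed = pick(raw$seed, 0L))
}

#' Default experiment configuration
#'
#' @return the [ExperimentConfig-class] obtained from an empty config file.
#' @export
defaultConfig <- function() {
  configFromList(structure(list(), names = character()))
}
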