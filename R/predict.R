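#' @include train.R
NULL

#' Classify every object of one image
#'
#' Patches are extracted and normalized exactly as at training time (the
#' settings live in the model / checkpoint sidecar); the predicted class is
#' the argmax over logits with ties broken toward the smallest class index,
#' and the confidence is the max softmax probability. Prediction is pure:
#' the same model and inputs always give the identical table.
#'
#' @param model a [MinimalistCNN-class].
#' @param image an [ImageVolume-class].
#' @param mask the paired [LabelMask-class].
#' @param batchSize forward-pass batch size (memory knob only).
#' @return data.frame(image_id, object_id, class, confidence), one row per
#'   distinct nonzero mask id.
#' @export
predictObjects <- function(model, image, mask, batchSize = 64L) {
  spec <- model@spec
  ps <- model@patchSettings
  expectC <- nChannels(image) + as.integer(isTRUE(ps$includeMaskChannel))
  if (expectC != spec@inChannels)
    stop(sprintf(
      "channel mismatch: checkpoint expects %d input channels but image + mask channel give %d",
      spec@inChannels, expectC))
  pset <- buildPatchSet(image, mask, "all", spec@patchSize,
                        includeMaskChannel = isTRUE(ps$includeMaskChannel),
                        normalization = ps$normalization)
  n <- nObjects(pset)
  if (n == 0L)
    return(data.frame(image_id = character(), object_id = integer(),
                      class = integer(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  cls <- integer(n)
  conf <- numeric(n)
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    logits <- predictLogits(model, pset[idx])
    P <- t(softmaxCols(t(logits)))
    cls[idx] <- max.col(logits, ties.method = "first")
    conf[idx] <- P[cbind(seq_along(idx), cls[idx])]
  }
  data.frame(image_id = imageId(mask), object_id = objectIds(pset),
             class = cls, confidence = conf, stringsAsFactors = FALSE)
}

#' Render a prediction table as a class mask
#'
#' Voxelwise relabeling: each object's voxels take its predicted class;
#' the nonzero support is identical to the label mask's.
#'
#' @param mask a [LabelMask-class].
#' @param table prediction data.frame covering every id in the mask.
#' @return a [ClassMask-class].
#' @export
renderClassMask <- function(mask, table) {
  ids <- objectIds(mask)
  m <- match(ids, table$object_id)
  if (anyNA(m))
    stop("prediction table is missing object id(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  lut <- integer(max(ids) + 1L)              # lut[id + 1] = class
  lut[ids + 1L] <- as.integer(table$class[m])
  lab <- maskLabels(mask)
  out <- array(0L, dim(lab))
  nz <- lab > 0
  out[nz] <- lut[lab[nz] + 1L]
  new("ClassMask", classes = out, imageId = imageId(mask))
}

#' Per-class object counts of a prediction table
#'
#' @param table prediction data.frame.
#' @return named integer vector class -> count (counts sum to the number
#'   of objects; empty table gives an empty vector).
#' @export
countPerClass <- function(table) {
  if (nrow(table) == 0L) return(structure(integer(), names = character()))
  tb <- table(table$class)
  structure(as.integer(tb), names = names(tb))
}

#' Classify every image of a folder
#'
#' Images and masks are paired by identical filename stem (the pairing must
#' be a bijection or the run aborts with a listing). For each pair a class
#' mask and a prediction table are written, plus one combined per-class
#' counts CSV.
#'
#' @param model a [MinimalistCNN-class] (or base path of a checkpoint).
#' @param imagesDir,masksDir input folders of TIFFs.
#' @param outDir output folder (created if needed).
#' @param white white point for reading intensities (see [readImageVolume()]).
#' @return invisibly, a summary data.frame(image_id, n_objects, then one
#'   column per class).
#' @export
predictFolder <- function(model, imagesDir, masksDir, outDir, white = 255) {
  if (is.character(model)) model <- loadCheckpoint(model)
  pairs <- pairFolders(imagesDir, masksDir)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rows <- list()
  allCls <- seq_len(model@spec@nClasses)
  for (i in seq_len(nrow(pairs))) {
    pr <- readPair(pairs$image[i], pairs$mask[i], white = white)
    ## the mask file carries the stem-derived id; keep image consistent
    tab <- predictObjects(model, pr$image, pr$mask)
    cm <- renderClassMask(pr$mask, tab)
    writeClassMask(cm, file.path(outDir, paste0(pairs$stem[i], "_classmask.tif")))
    writePredictionTable(tab, file.path(outDir,
                                        paste0(pairs$stem[i], "_predictions.csv")))
    cnt <- countPerClass(tab)
    row <- c(list(image_id = pairs$stem[i], n_objects = nrow(tab)),
             as.list(structure(as.integer(cnt[as.character(allCls)]),
                               names = paste0("class_", allCls))))
    row[is.na(row)] <- 0L
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  summary <- if (length(rows) == 0L) {
    data.frame(image_id = character(), n_objects = integer())
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(summary, file.path(outDir, "class_counts.csv"),
                   row.names = FALSE)
  invisible(summary)
}

#' Accuracy of a prediction table against ground truth
#'
#' @param truth named integer vector (object id -> class) or an
#'   [AnnotationSet-class].
#' @param table prediction data.frame.
#' @param exclude optional object ids to leave out (e.g. the training
#'   labels, to obtain held-out accuracy).
#' @return fraction of objects predicted correctly.
#' @export
predictionAccuracy <- function(truth, table, exclude = NULL) {
  if (is(truth, "AnnotationSet")) {
    r <- annotations(truth)
    truth <- structure(r$class, names = r$object_id)
  }
  keep <- !(table$object_id %in% exclude)
  tab <- table[keep, , drop = FALSE]
  tv <- truth[as.character(tab$object_id)]
  if (anyNA(tv))
    stop("truth is missing object id(s): ",
         paste(tab$object_id[is.na(tv)], collapse = ", "))
  mean(tab$class == tv)
}
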