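#' @include patches.R
NULL

#' Construct an AnnotationSet
#'
#' @param records data.frame with columns image_id, object_id, class and
#'   optionally provenance (default "manual"); NULL gives an empty set.
#' @return an [AnnotationSet-class].
#' @export
AnnotationSet <- function(records = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(image_id = character(), object_id = integer(),
                          class = integer(), provenance = character(),
                          stringsAsFactors = FALSE)
  } else {
    if (is.null(records$provenance)) records$provenance <- "manual"
    records <- data.frame(image_id = as.character(records$image_id),
                          object_id = as.integer(records$object_id),
                          class = as.integer(records$class),
                          provenance = as.character(records$provenance),
                          stringsAsFactors = FALSE)
  }
  new("AnnotationSet", records = records)
}

#' Randomly sample object ids from a mask
#'
#' Uniform sampling without replacement, deterministic given the seed:
#' the headless analogue of letting the annotation tool pick regions of
#' interest at random.
#'
#' @param mask a [LabelMask-class].
#' @param n how many ids to draw.
#' @param seed RNG seed.
#' @return integer vector of n object ids.
#' @export
sampleObjects <- function(mask, n, seed) {
  ids <- objectIds(mask)
  if (n > length(ids))
    stop(sprintf("cannot sample %d objects: only %d available", n,
                 length(ids)))
  set.seed(as.integer(seed))
  ids[sample.int(length(ids), n)]
}

#' Assign (or overwrite) one object's class label
#'
#' Labels are numbers from 1 to 9 (the maximum number of classes); the
#' latest assignment for a given (image_id, object_id) pair wins.
#'
#' @param ann an [AnnotationSet-class].
#' @param imageId,objectId the record key.
#' @param class integer 1..9.
#' @param provenance one of "manual", "corrected", "confirmed".
#' @return the updated [AnnotationSet-class].
#' @export
assignLabel <- function(ann, imageId, objectId, class,
                        provenance = "manual") {
  if (class < 1 || class > 9)
    stop("class must be between 1 and 9, got ", class)
  r <- annotations(ann)
  hit <- r$image_id == imageId & r$object_id == objectId
  if (any(hit)) {
    r$class[hit] <- as.integer(class)
    r$provenance[hit] <- provenance
  } else {
    r <- rbind(r, data.frame(image_id = as.character(imageId),
                             object_id = as.integer(objectId),
                             class = as.integer(class),
                             provenance = provenance,
                             stringsAsFactors = FALSE))
  }
  new("AnnotationSet", records = r)
}

#' Merge user corrections of a prediction into the training labels
#'
#' The human-in-the-loop step: after a prediction pass the user corrects
#' (or explicitly confirms) some predicted labels; the output training set
#' is the union of the existing manual annotations, the corrections
#' (provenance "corrected") and the explicitly confirmed predictions
#' (provenance "confirmed"). Unreviewed predictions are never promoted to
#' training labels, which avoids a confirmation-bias feedback loop.
#'
#' @param ann the existing [AnnotationSet-class] (manual labels).
#' @param predictions prediction table (data.frame with image_id,
#'   object_id, class).
#' @param corrections [AnnotationSet-class] of corrected labels; every
#'   record must reference a predicted object.
#' @param confirm optional data.frame(image_id, object_id) of predictions
#'   the user confirmed as-is.
#' @return the merged [AnnotationSet-class].
#' @export
mergeCorrections <- function(ann, predictions, corrections,
                             confirm = NULL) {
  key <- function(im, ob) paste(im, ob, sep = "\r")
  pkey <- key(predictions$image_id, predictions$object_id)
  cr <- annotations(corrections)
  bad <- !key(cr$image_id, cr$object_id) %in% pkey
  if (any(bad))
    stop("correction(s) for unknown object(s): ",
         paste(sprintf("%s/%s", cr$image_id[bad], cr$object_id[bad]),
               collapse = ", "))
  out <- ann
  for (i in seq_len(nrow(cr)))
    out <- assignLabel(out, cr$image_id[i], cr$object_id[i], cr$class[i],
                       provenance = "corrected")
  if (!is.null(confirm) && nrow(confirm) > 0) {
    ck <- key(confirm$image_id, confirm$object_id)
    m <- match(ck, pkey)
    if (anyNA(m))
      stop("confirmation(s) for unknown object(s): ",
           paste(ck[is.na(m)], collapse = ", "))
    for (i in seq_along(m))
      out <- assignLabel(out, predictions$image_id[m[i]],
                         predictions$object_id[m[i]],
                         predictions$class[m[i]], provenance = "confirmed")
  }
  out
}

#' Build annotations from a synthetic scene's ground truth
#'
#' The headless analogue of manual annotation: import the generator's
#' truth, optionally restricted to a sampled subset of object ids.
#'
#' @param scene a [SyntheticScene-class].
#' @param ids object ids to label (default: all).
#' @return an [AnnotationSet-class] with provenance "manual".
#' @export
annotationsFromTruth <- function(scene, ids = NULL) {
  truth <- sceneTruth(scene)
  if (is.null(ids)) ids <- as.integer(names(truth))
  cls <- truth[as.character(ids)]
  if (anyNA(cls))
    stop("id(s) absent from scene truth: ",
         paste(ids[is.na(cls)], collapse = ", "))
  AnnotationSet(data.frame(image_id = imageId(sceneImage(scene)),
                           object_id = as.integer(ids),
                           class = as.integer(cls),
                           provenance = "manual",
                           stringsAsFactors = FALSE))
}

#' Stratified sample of annotation labels from scene truth
#'
#' Draws \code{nPerClass} object ids per class (deterministic given seed)
#' and returns them as an annotation set, emulating a user labeling a
#' balanced handful of objects.
#'
#' @param scene a [SyntheticScene-class].
#' @param nPerClass labels per class.
#' @param seed RNG seed.
#' @return an [AnnotationSet-class].
#' @export
sampleTruthAnnotations <- function(scene, nPerClass, seed) {
  truth <- sceneTruth(scene)
  set.seed(as.integer(seed))
  ids <- unlist(lapply(sort(unique(truth)), function(k) {
    pool <- as.integer(names(truth)[truth == k])
    if (nPerClass > length(pool))
      stop(sprintf("class %d has only %d objects, cannot sample %d", k,
                   length(pool), nPerClass))
    pool[sample.int(length(pool), nPerClass)]
  }))
  annotationsFromTruth(scene, ids = sort(ids))
}
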