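#' @include AllGenerics.R
NULL

#' Construct an ImageVolume
#'
#' Accepts a bare 2D matrix (promoted to one channel), a 3D \code{(C,Y,X)}
#' array, or a 4D \code{(C,Z,Y,X)} array.
#'
#' @param pixels numeric matrix or array, channel-first.
#' @param imageId identifier string (filename stem convention).
#' @return an [ImageVolume-class].
#' @export
ImageVolume <- function(pixels, imageId = "image") {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(1L, dim(pixels)))
  }
  new("ImageVolume", pixels = pixels, imageId = imageId)
}

#' Construct a LabelMask
#'
#' @param labels integer matrix or array (Y,X) / (Z,Y,X); 0 = background.
#' @param imageId identifier string.
#' @return a [LabelMask-class].
#' @export
LabelMask <- function(labels, imageId = "image") {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, imageId = imageId)
}

fileStem <- function(path) {
  sub("\\.[^.]*$", "", basename(path))
}

## libtiff flags our non-RGB sample counts (e.g. 2-channel pages) with a
## harmless ExtraSamples note; silence just that
quietTIFF <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("ExtraSamples|Photometric", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

## Intensities are stored as 16-bit TIFF samples scaled by a white point:
## write k = round(x/white * 65535), read back k/65535 * white. Values that
## sit on that 16-bit grid round-trip bit-exactly; anything else is
## quantized to ~white/65535 (immaterial downstream: patches are min-max
## normalized or globally rescaled before classification).

#' Read an intensity image from TIFF
#'
#' Multi-page files are read as 3D (pages = Z); the per-page sample axis, if
#' any, becomes the channel axis, normalized to first position.
#'
#' @param path TIFF file.
#' @param white white point multiplied back into the stored [0,1] values
#'   (default 255, matching [writeImageVolume()]).
#' @return an [ImageVolume-class].
#' @export
readImageVolume <- function(path, white = 255) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- quietTIFF(tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (is.matrix(p)) p <- array(p, c(dim(p), 1L))
    aperm(p, c(3L, 1L, 2L))            # (Y,X,C) -> (C,Y,X)
  })
  px <- if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    d <- dim(pages[[1L]])
    out <- array(0, c(d[1L], length(pages), d[2L], d[3L]))  # (C,Z,Y,X)
    for (z in seq_along(pages)) out[, z, , ] <- pages[[z]]
    out
  }
  ImageVolume(px * white, imageId = fileStem(path))
}

#' Write an intensity image to TIFF
#'
#' Stored as 16-bit samples with values scaled into [0,1] by \code{white}
#' (values outside [0, white] are clamped; the 16-bit grid gives a
#' resolution of white/65535). 3D volumes become multi-page files (one
#' page per Z slice); channels become per-page samples, so at most 4
#' channels can be written.
#'
#' @param image an [ImageVolume-class].
#' @param path output file.
#' @param white white point divisor (default 255).
#' @return invisibly, \code{path}.
#' @export
writeImageVolume <- function(image, path, white = 255) {
  px <- pixels(image)
  d <- dim(px)
  if (d[1L] > 4L)
    stop("TIFF output supports at most 4 channels, got ", d[1L])
  px <- round(pmin(pmax(px / white, 0), 1) * 65535) / 65535
  toPage <- function(a) aperm(a, c(2L, 3L, 1L))  # (C,Y,X) -> (Y,X,C)
  what <- if (length(d) == 3L) {
    toPage(px)
  } else {
    lapply(seq_len(d[2L]), function(z) {
      slice <- px[, z, , , drop = FALSE]
      dim(slice) <- d[c(1L, 3L, 4L)]
      toPage(slice)
    })
  }
  tiff::writeTIFF(what, path, bits.per.sample = 16L)
  invisible(path)
}

readIntegerTIFF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- quietTIFF(tiff::readTIFF(path, all = TRUE, as.is = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop("mask TIFF must be single-sample, got ", dim(p)[3L], " samples")
      p <- p[, , 1L]
    }
    if (any(p != floor(p)))
      stop("mask TIFF is not integer-valued: ", path)
    p
  })
  arr <- if (length(pages) == 1L) {
    pages[[1L]]
  } else {
    d <- dim(pages[[1L]])
    out <- array(0L, c(length(pages), d))
    for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
    out
  }
  storage.mode(arr) <- "integer"
  arr
}

writeIntegerTIFF <- function(arr, path) {
  if (max(arr) > 65535L)
    stop("integer TIFF output supports values up to 65535, got ", max(arr))
  what <- if (length(dim(arr)) == 2L) {
    arr / 65535
  } else {
    lapply(seq_len(dim(arr)[1L]), function(z) arr[z, , ] / 65535)
  }
  tiff::writeTIFF(what, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask from TIFF
#'
#' The mask's image id identifies the intensity image it segments: a
#' trailing \code{_mask} in the filename stem is stripped, so
#' \code{cells_mask.tif} pairs with annotations for image \code{cells}.
#'
#' @param path TIFF file holding 8/16-bit integers; multi-page = Z.
#' @return a [LabelMask-class].
#' @export
readLabelMask <- function(path) {
  LabelMask(readIntegerTIFF(path),
            imageId = sub("_mask$", "", fileStem(path)))
}

#' Write a label mask to TIFF (16-bit, bit-exact round trip)
#'
#' @param mask a [LabelMask-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeLabelMask <- function(mask, path) {
  writeIntegerTIFF(maskLabels(mask), path)
}

#' Read and pair an intensity image with its label mask
#'
#' The channel axis of the image is inferred and normalized to first
#' position; the mask's spatial shape must equal the image's spatial shape.
#'
#' @param imagePath,maskPath TIFF files.
#' @param white white point for the intensity image (see [readImageVolume()]).
#' @return list(image = [ImageVolume-class], mask = [LabelMask-class]).
#' @export
readPair <- function(imagePath, maskPath, white = 255) {
  img <- readImageVolume(imagePath, white = white)
  msk <- readLabelMask(maskPath)
  si <- spatialDim(img)
  sm <- spatialDim(msk)
  if (!identical(as.integer(si), as.integer(sm)))
    stop(sprintf("image/mask shape mismatch: image spatial (%s) vs mask (%s)",
                 paste(si, collapse = ","), paste(sm, collapse = ",")))
  list(image = img, mask = msk)
}

#' Write a class mask to TIFF
#'
#' Values are class ids 0..9 (0 = background), written 16-bit so the file
#' round-trips bit-exactly; 3D masks become multi-page files with one page
#' per Z slice.
#'
#' @param mask a [ClassMask-class] (or integer array of class ids).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeClassMask <- function(mask, path) {
  arr <- if (is(mask, "ClassMask")) maskLabels(mask) else mask
  if (min(arr) < 0 || max(arr) > 9)
    stop("class mask values must be in 0..9")
  writeIntegerTIFF(arr, path)
}

#' Read a class mask from TIFF
#'
#' @param path TIFF file written by [writeClassMask()].
#' @return a [ClassMask-class].
#' @export
readClassMask <- function(path) {
  new("ClassMask", classes = readIntegerTIFF(path), imageId = fileStem(path))
}

#' Read / write annotation files
#'
#' Annotations are stored as a JSON array of records
#' \code{{"image_id": str, "object_id": int, "class": int 1..9}} with an
#' optional \code{"provenance"} field (defaulting to "manual").
#'
#' @param path JSON file.
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(rec) == 0L) return(AnnotationSet())
  if (is.null(rec$provenance)) rec$provenance <- "manual"
  AnnotationSet(data.frame(image_id = as.character(rec$image_id),
                           object_id = as.integer(rec$object_id),
                           class = as.integer(rec$class),
                           provenance = as.character(rec$provenance),
                           stringsAsFactors = FALSE))
}

#' @rdname readAnnotations
#' @param ann an [AnnotationSet-class].
#' @export
writeAnnotations <- function(ann, path) {
  jsonlite::write_json(annotations(ann), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read / write prediction tables
#'
#' CSV with header \code{image_id,object_id,class,confidence}.
#'
#' @param path CSV file.
#' @return data.frame with those four columns.
#' @export
readPredictionTable <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "object_id", "class", "confidence")
  if (!all(need %in% names(tb)))
    stop("prediction table must have columns: ", paste(need, collapse = ", "))
  tb$image_id <- as.character(tb$image_id)
  tb$object_id <- as.integer(tb$object_id)
  tb$class <- as.integer(tb$class)
  tb[need]
}

#' @rdname readPredictionTable
#' @param table prediction data.frame.
#' @export
writePredictionTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair image and mask files across two folders by filename stem
#'
#' The association must be a bijection; unmatched stems on either side abort
#' the run with a listing.
#'
#' @param imagesDir,masksDir folders of TIFF files.
#' @return data.frame(stem, image, mask) sorted by stem.
#' @export
pairFolders <- function(imagesDir, masksDir) {
  imgs <- list.files(imagesDir, pattern = "\\.tiff?$", full.names = TRUE)
  msks <- list.files(masksDir, pattern = "\\.tiff?$", full.names = TRUE)
  si <- vapply(imgs, fileStem, "")
  sm <- vapply(msks, fileStem, "")
  bad <- c(setdiff(si, sm), setdiff(sm, si))
  if (length(bad) > 0)
    stop("unmatched image/mask stems: ", paste(sort(unique(bad)), collapse = ", "))
  if (anyDuplicated(si) || anyDuplicated(sm))
    stop("duplicate stems within a folder")
  o <- order(si)
  data.frame(stem = si[o], image = imgs[o],
             mask = msks[match(si[o], sm)], stringsAsFactors = FALSE)
}

#' Save a reproducibility manifest for a run
#'
#' Records the full experiment configuration, its seed and the MD5 hash of
#' every output file, so a run can be replayed and checked bit-exactly for
#' its deterministic stages.
#'
#' @param config an [ExperimentConfig-class].
#' @param outputs named character vector/list of output file paths.
#' @param path manifest destination (JSON).
#' @return invisibly, \code{path}.
#' @export
saveRunManifest <- function(config, outputs, path) {
  outputs <- as.list(outputs)
  hashes <- lapply(outputs, function(p) {
    list(path = as.character(p),
         md5 = unname(tools::md5sum(as.character(p))))
  })
  jsonlite::write_json(
    list(config = configAsList(config), seed = config@seed, outputs = hashes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
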