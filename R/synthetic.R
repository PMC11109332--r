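#' @include config.R
NULL

#' Construct a SyntheticScene
#'
#' @param image [ImageVolume-class]; @param mask [LabelMask-class].
#' @param truth named integer vector object id -> class.
#' @param params generator parameter list.
#' @return a [SyntheticScene-class].
#' @export
SyntheticScene <- function(image, mask, truth, params = list()) {
  new("SyntheticScene", image = image, mask = mask,
      truth = structure(as.integer(truth), names = names(truth)),
      params = params)
}

placeCenters <- function(n, extents, radii, margin = 1L) {
  ## rejection sampling of non-overlapping bounding spheres
  radii <- as.integer(ceiling(radii))
  centers <- matrix(0, 0, length(extents))
  placedR <- numeric(0)
  tries <- 0L
  maxTries <- 300L * n
  while (nrow(centers) < n && tries < maxTries) {
    tries <- tries + 1L
    i <- nrow(centers) + 1L
    r <- radii[i]
    c0 <- vapply(extents, function(e) sample.int(e - 2L * r, 1L) + r, 0L)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt(rowSums((centers - matrix(c0, nrow(centers),
                                          length(extents), byrow = TRUE))^2))
      ok <- all(d > placedR + r + margin)
    }
    if (ok) {
      centers <- rbind(centers, c0)
      placedR <- c(placedR, r)
    }
  }
  if (nrow(centers) < n)
    stop(sprintf("could not place %d objects without overlap (placed %d); %s",
                 n, nrow(centers), "reduce n or radii, or enlarge the canvas"))
  centers
}

#' Generate a two-class gray-level cell scene
#'
#' Disks at non-overlapping random centers on a zero background; the two
#' classes differ only in interior mean gray level (plus i.i.d. Gaussian
#' noise), the classic case where a simple mean-intensity feature is fully
#' discriminant.
#'
#' @param nCells number of disks (classes balanced).
#' @param meanA,meanB interior mean gray levels of the two classes.
#' @param noiseSd Gaussian noise standard deviation.
#' @param radiusRange integer (min, max) disk radius.
#' @param canvas (Y, X) canvas extents.
#' @param seed RNG seed; the scene is a pure function of arguments + seed.
#' @return a [SyntheticScene-class] (single-channel image, classes 1/2).
#' @export
genCells <- function(nCells = 120, meanA = 80, meanB = 180, noiseSd = 5,
                     radiusRange = c(5L, 9L), canvas = c(256L, 256L),
                     seed = 1) {
  set.seed(as.integer(seed))
  radii <- sample(seq.int(radiusRange[1], radiusRange[2]), nCells,
                  replace = TRUE)
  centers <- placeCenters(nCells, canvas, radii)
  classes <- sample(rep(1:2, length.out = nCells))
  img <- matrix(0, canvas[1], canvas[2])
  msk <- matrix(0L, canvas[1], canvas[2])
  means <- c(meanA, meanB)
  for (i in seq_len(nCells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
    ys <- (cy - r):(cy + r)
    xs <- (cx - r):(cx + r)
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    inside <- d2 <= r^2
    vals <- means[classes[i]] +
      (if (noiseSd > 0) stats::rnorm(sum(inside), 0, noiseSd) else 0)
    sub <- img[ys, xs]; sub[inside] <- vals; img[ys, xs] <- sub
    subm <- msk[ys, xs]; subm[inside] <- i; msk[ys, xs] <- subm
  }
  SyntheticScene(
    ImageVolume(img, "cells"), LabelMask(msk, "cells"),
    structure(classes, names = seq_len(nCells)),
    params = list(kind = "cells", nCells = nCells, meanA = meanA,
                  meanB = meanB, noiseSd = noiseSd,
                  radiusRange = radiusRange, canvas = canvas, seed = seed))
}

orientedKernel <- function(thetaDeg, sigmaLong = 5, sigmaShort = 0.8,
                           halfSize = 10L) {
  th <- thetaDeg * pi / 180
  dy <- matrix(rep(-halfSize:halfSize, 2L * halfSize + 1L), 2L * halfSize + 1L)
  dx <- t(dy)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  k <- exp(-u^2 / (2 * sigmaLong^2) - v^2 / (2 * sigmaShort^2))
  k / sum(k)
}

fftConvSame <- function(field, kernel) {
  n <- dim(field)
  kp <- matrix(0, n[1], n[2])
  hs <- (dim(kernel)[1] - 1L) / 2L
  ## embed kernel centered at (1,1) with circular wrap
  idx <- function(d, n) ((d + n) %% n) + 1L
  for (a in -hs:hs) for (b in -hs:hs)
    kp[idx(a, n[1]), idx(b, n[2])] <- kernel[a + hs + 1L, b + hs + 1L]
  Re(stats::fft(stats::fft(field) * stats::fft(kp), inverse = TRUE)) /
    prod(n)
}

#' Generate a two-class oriented-texture scene
#'
#' A grid of square tiles; each tile is filled with an anisotropic texture
#' (white Gaussian noise smoothed by an elongated oriented Gaussian kernel
#' at the tile's class angle), then affinely standardized per tile to a
#' common target mean and variance. By construction first and second
#' moments carry no class information; only the orientation does.
#'
#' @param thetaA,thetaB class orientations in degrees (must differ mod 180).
#' @param nTiles number of tiles (classes balanced).
#' @param tile (Y, X) tile extents.
#' @param seed RNG seed.
#' @param targetMean,targetSd the common per-tile moments.
#' @param layout "random" assigns classes randomly across the grid;
#'   "segregated" puts class 1 in the left half of the grid and class 2 in
#'   the right half (a spatial confound, useful for studying classifiers
#'   that consume position features).
#' @return a [SyntheticScene-class].
#' @export
genOrientedTextures <- function(thetaA = 0, thetaB = 90, nTiles = 156,
                                tile = c(32L, 32L), seed = 1,
                                targetMean = 128, targetSd = 30,
                                layout = c("random", "segregated")) {
  layout <- match.arg(layout)
  if ((thetaA - thetaB) %% 180 == 0)
    stop("thetaA and thetaB must differ (mod 180)")
  if (any(tile < 4L)) stop("degenerate tile shape: ", paste(tile, collapse = "x"))
  set.seed(as.integer(seed))
  ncols <- ceiling(sqrt(nTiles))
  nrows <- ceiling(nTiles / ncols)
  canvas <- c(nrows * tile[1], ncols * tile[2])
  img <- matrix(0, canvas[1], canvas[2])
  msk <- matrix(0L, canvas[1], canvas[2])
  tileCol <- ((seq_len(nTiles) - 1L) %% ncols) + 1L
  classes <- if (layout == "random") {
    sample(rep(1:2, length.out = nTiles))
  } else {
    ifelse(tileCol <= ncols / 2, 1L, 2L)
  }
  kerns <- list(orientedKernel(thetaA), orientedKernel(thetaB))
  hs <- 10L
  for (i in seq_len(nTiles)) {
    rw <- (i - 1L) %/% ncols
    cl <- (i - 1L) %% ncols
    noise <- matrix(stats::rnorm((tile[1] + 2L * hs) * (tile[2] + 2L * hs)),
                    tile[1] + 2L * hs)
    sm <- fftConvSame(noise, kerns[[classes[i]]])
    t0 <- sm[(hs + 1L):(hs + tile[1]), (hs + 1L):(hs + tile[2])]
    t0 <- (t0 - mean(t0)) / stats::sd(t0) * targetSd + targetMean
    ys <- (rw * tile[1] + 1L):((rw + 1L) * tile[1])
    xs <- (cl * tile[2] + 1L):((cl + 1L) * tile[2])
    img[ys, xs] <- t0
    msk[ys, xs] <- i
  }
  SyntheticScene(
    ImageVolume(img, "textures"), LabelMask(msk, "textures"),
    structure(classes, names = seq_len(nTiles)),
    params = list(kind = "textures", thetaA = thetaA, thetaB = thetaB,
                  nTiles = nTiles, tile = tile, seed = seed,
                  targetMean = targetMean, targetSd = targetSd,
                  layout = layout))
}

#' Generate a 3D two-class blob scene
#'
#' Ellipsoidal blobs in a 3D volume; the classes differ either by interior
#' mean intensity or by axis elongation, exercising the full 3D code path
#' (multi-page volumes, 3D patches, 3D convolutions) without any external
#' dataset.
#'
#' @param nBlobs number of blobs (classes balanced).
#' @param twoClassRule "intensity" (means differ by \code{delta}) or
#'   "elongation" (class 2 stretched by \code{elongation} along X).
#' @param canvas (Z, Y, X) extents.
#' @param seed RNG seed.
#' @param delta intensity gap for the intensity rule.
#' @param elongation axis-ratio factor for the elongation rule.
#' @param noiseSd Gaussian interior noise.
#' @param radiusRange integer (min, max) base semi-axis.
#' @return a [SyntheticScene-class].
#' @export
genBlobs3d <- function(nBlobs = 40, twoClassRule = c("intensity", "elongation"),
                       canvas = c(48L, 64L, 64L), seed = 1, delta = 100,
                       elongation = 2.5, noiseSd = 5,
                       radiusRange = c(3L, 5L)) {
  twoClassRule <- match.arg(twoClassRule)
  set.seed(as.integer(seed))
  base <- sample(seq.int(radiusRange[1], radiusRange[2]), nBlobs,
                 replace = TRUE)
  classes <- sample(rep(1:2, length.out = nBlobs))
  ax <- matrix(base, nBlobs, 3L)                     # semi-axes (Z,Y,X)
  if (twoClassRule == "elongation")
    ax[classes == 2L, 3L] <- ceiling(ax[classes == 2L, 3L] * elongation)
  bound <- apply(ax, 1L, max)
  centers <- placeCenters(nBlobs, canvas, bound)
  means <- if (twoClassRule == "intensity") c(130 - delta / 2, 130 + delta / 2)
           else c(130, 130)
  img <- array(0, canvas)
  msk <- array(0L, canvas)
  for (i in seq_len(nBlobs)) {
    c0 <- centers[i, ]
    a <- ax[i, ]
    zs <- max(1, c0[1] - a[1]):min(canvas[1], c0[1] + a[1])
    ys <- max(1, c0[2] - a[2]):min(canvas[2], c0[2] + a[2])
    xs <- max(1, c0[3] - a[3]):min(canvas[3], c0[3] + a[3])
    g <- expand.grid(z = zs, y = ys, x = xs)
    inside <- ((g$z - c0[1]) / a[1])^2 + ((g$y - c0[2]) / a[2])^2 +
      ((g$x - c0[3]) / a[3])^2 <= 1
    sel <- g[inside, ]
    lin <- sel$z + canvas[1] * (sel$y - 1L) + canvas[1] * canvas[2] * (sel$x - 1L)
    img[lin] <- means[classes[i]] +
      (if (noiseSd > 0) stats::rnorm(nrow(sel), 0, noiseSd) else 0)
    msk[lin] <- i
  }
  dim(img) <- canvas
  px <- array(img, c(1L, canvas))
  SyntheticScene(
    new("ImageVolume", pixels = px, imageId = "blobs3d"),
    LabelMask(msk, "blobs3d"),
    structure(classes, names = seq_len(nBlobs)),
    params = list(kind = "blobs3d", nBlobs = nBlobs,
                  twoClassRule = twoClassRule, canvas = canvas, seed = seed,
                  delta = delta, elongation = elongation, noiseSd = noiseSd,
                  radiusRange = radiusRange))
}

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Rotate a scene by 90 degrees (counter-clockwise, in the Y/X plane)
#'
#' Object ids and ground truth are preserved; useful for studying
#' rotation robustness and spatial confounding.
#'
#' @param scene a [SyntheticScene-class] (2D).
#' @return the rotated [SyntheticScene-class].
#' @export
rotateScene90 <- function(scene) {
  px <- pixels(sceneImage(scene))
  d <- dim(px)
  if (length(d) != 3L) stop("rotateScene90 supports 2D scenes")
  rot <- array(0, c(d[1], d[3], d[2]))
  for (ch in seq_len(d[1])) rot[ch, , ] <- rot90ccw(px[ch, , ])
  msk <- rot90ccw(maskLabels(sceneMask(scene)))
  SyntheticScene(
    new("ImageVolume", pixels = rot, imageId = imageId(sceneImage(scene))),
    LabelMask(msk, imageId(sceneMask(scene))),
    sceneTruth(scene),
    params = c(scene@params, list(rotated90 = TRUE)))
}

#' Export a scene to disk (image TIFF + mask TIFF + truth JSON)
#'
#' The truth file uses the annotation schema with every object labeled.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param stem filename stem (defaults to the scene's image id).
#' @return invisibly, named character vector of the three paths.
#' @export
writeScene <- function(scene, dir, stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- imageId(sceneImage(scene))
  ip <- file.path(dir, paste0(stem, ".tif"))
  mp <- file.path(dir, paste0(stem, "_mask.tif"))
  tp <- file.path(dir, paste0(stem, "_truth.json"))
  writeImageVolume(sceneImage(scene), ip)
  writeLabelMask(sceneMask(scene), mp)
  writeAnnotations(annotationsFromTruth(scene), tp)
  invisible(c(image = ip, mask = mp, truth = tp))
}
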