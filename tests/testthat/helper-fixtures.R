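# Shared fixtures, built in code.

# snap values onto the 16-bit storage grid so TIFF round trips are bit-exact
q16 <- function(x, white = 1) {
  round(x / white * 65535) / 65535 * white
}

# a tiny deterministic image/mask pair: two 3x3 squares (ids 4 and 7)
tinyPair <- function(id = "tiny") {
  img <- matrix(0, 20, 24)
  img[3:5, 3:5] <- 100
  img[10:12, 15:17] <- 200
  msk <- matrix(0L, 20, 24)
  msk[3:5, 3:5] <- 4L
  msk[10:12, 15:17] <- 7L
  list(image = ImageVolume(img, id), mask = LabelMask(msk, id))
}

tinySpec2d <- function(depth = 2, width = 4, inChannels = 2, nClasses = 2,
                       patchSize = 8) {
  classifierSpec(dim = 2, depth = depth, width = width,
                 inChannels = inChannels, nClasses = nClasses,
                 patchSize = patchSize)
}

# small labeled patch set of pure-noise patches (for optimization tests)
noisePatchSet <- function(n = 8, C = 1, s = 8, K = 2, seed = 1) {
  set.seed(seed)
  new("PatchSet",
      patches = array(runif(C * s * s * n), c(C, s, s, n)),
      labels = rep(seq_len(K), length.out = n),
      objectIds = seq_len(n), imageId = "noise",
      patchSize = as.integer(c(s, s)))
}

# per-tile orientation statistic: gradient energy along x vs along y
orientationEnergy <- function(img2d, mask2d, id) {
  t0 <- img2d[]
  sel <- mask2d == id
  # work on the bounding box of the tile
  rc <- which(sel, arr.ind = TRUE)
  t0 <- img2d[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2])]
  ex <- mean((t0[, -1] - t0[, -ncol(t0)])^2)
  ey <- mean((t0[-1, ] - t0[-nrow(t0), ])^2)
  log(ex / ey)
}
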