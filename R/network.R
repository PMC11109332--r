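#' @include annotations.R
NULL

## ---------------------------------------------------------------------------
## Minimalist CNN engine.
##
## Architecture: depth d blocks of [conv k^dim (stride 1, same zero padding)
## -> ReLU -> max-pool 2], constant width w, then global average pooling and
## an affine map to K logits. Convolutions are evaluated as im2col gathers
## followed by BLAS matrix products; the backward pass to a layer's input is
## the transposed-kernel convolution, evaluated the same way. Geometry
## (gather indices) is cached per (channels, spatial shape, kernel) so the
## cost per batch is a handful of GEMMs.
## ---------------------------------------------------------------------------

.segpatchPlans <- new.env(parent = emptyenv())

convPlan <- function(C, spatial, k) {
  sig <- paste(c(C, spatial, k), collapse = "x")
  hit <- .segpatchPlans[[sig]]
  if (!is.null(hit)) return(hit)
  nd <- length(spatial)
  p <- (k - 1L) %/% 2L
  P <- spatial + 2L * p
  prodP <- cumprod(c(1L, P[-nd]))
  prodK <- cumprod(c(1L, rep(k, nd - 1L)))
  kg <- as.matrix(expand.grid(rep(list(0:(k - 1L)), nd)))  # first axis fastest
  rowOff <- as.vector(outer(seq_len(C), C * as.vector(kg %*% prodP), "+"))
  og <- as.matrix(expand.grid(lapply(spatial, function(s) 0:(s - 1L))))
  colOff <- C * as.vector(og %*% prodP)
  idx <- outer(rowOff, colOff, "+")          # (C*k^nd, prod(spatial))
  storage.mode(idx) <- "integer"
  ## column index in W for the flipped kernel (transposed convolution)
  flipCol <- 1L + as.integer((k - 1L - kg) %*% prodK)  # per kernel offset
  plan <- list(C = C, spatial = spatial, k = k, p = p, P = P,
               rows = C * k^nd, cols = prod(spatial),
               idx = as.vector(idx), flipCol = flipCol,
               batches = new.env(parent = emptyenv()))
  .segpatchPlans[[sig]] <- plan
  plan
}

planBatchIdx <- function(plan, N) {
  key <- as.character(N)
  hit <- plan$batches[[key]]
  if (!is.null(hit)) return(hit)
  strideN <- plan$C * prod(plan$P)
  idxB <- rep.int(plan$idx, N) +
    rep(seq.int(0L, by = strideN, length.out = N), each = length(plan$idx))
  plan$batches[[key]] <- idxB
  idxB
}

padBatch <- function(A, plan, N) {
  ## A: (C, spatial..., N) -> zero-padded (C, P..., N)
  nd <- length(plan$spatial)
  if (plan$p == 0L) return(A)
  Ap <- array(0, c(plan$C, plan$P, N))
  core <- lapply(seq_len(nd), function(a) (plan$p + 1L):(plan$p + plan$spatial[a]))
  do.call(`[<-`, c(list(Ap), list(seq_len(plan$C)), core,
                   list(seq_len(N)), list(value = A)))
}

im2col <- function(A, plan, N) {
  Ap <- padBatch(A, plan, N)
  matrix(Ap[planBatchIdx(plan, N)], plan$rows, plan$cols * N)
}

## transposed-kernel weight matrix: (Cin, w*k^nd) from W (w, Cin*k^nd)
flipWeights <- function(W, plan) {
  w <- nrow(W)
  C <- plan$C
  nk <- length(plan$flipCol)
  ## element (c, (j,kappa)) = W[j, c + C*(flipCol[kappa]-1)]
  jj <- rep(seq_len(w), times = nk)
  kk <- rep(plan$flipCol, each = w)
  out <- matrix(0, C, w * nk)
  for (c in seq_len(C))
    out[c, ] <- W[cbind(jj, c + C * (kk - 1L))]
  out
}

poolOffsets <- function(nd) {
  as.matrix(expand.grid(rep(list(0:1), nd)))   # first axis fastest
}

maxPool2 <- function(A, nd) {
  ## A: (w, spatial..., N); halve every spatial axis (floor), track argmax.
  d <- dim(A)
  sp <- d[2:(nd + 1L)]
  ph <- sp %/% 2L
  N <- d[length(d)]
  offs <- poolOffsets(nd)
  sliceIdx <- function(o) {
    c(list(quote(expr = )),
      lapply(seq_len(nd), function(a) seq.int(1L + o[a], by = 2L,
                                              length.out = ph[a])),
      list(quote(expr = )))
  }
  best <- do.call(`[`, c(list(A), sliceIdx(offs[1L, ]), list(drop = FALSE)))
  arg <- array(1L, dim(best))
  for (i in 2:nrow(offs)) {
    cand <- do.call(`[`, c(list(A), sliceIdx(offs[i, ]), list(drop = FALSE)))
    sel <- cand > best
    best[sel] <- cand[sel]
    arg[sel] <- i
  }
  dim(best) <- c(d[1L], ph, N)
  dim(arg) <- dim(best)
  list(out = best, arg = arg, inSpatial = sp)
}

maxUnpool2 <- function(dOut, arg, inSpatial, nd) {
  d <- dim(dOut)
  ph <- d[2:(nd + 1L)]
  N <- d[length(d)]
  dA <- array(0, c(d[1L], inSpatial, N))
  offs <- poolOffsets(nd)
  sliceIdx <- function(o) {
    c(list(quote(expr = )),
      lapply(seq_len(nd), function(a) seq.int(1L + o[a], by = 2L,
                                              length.out = ph[a])),
      list(quote(expr = )))
  }
  for (i in seq_len(nrow(offs))) {
    sel <- arg == i
    if (!any(sel)) next
    sl <- do.call(`[`, c(list(dA), sliceIdx(offs[i, ]), list(drop = FALSE)))
    sl[sel] <- dOut[sel]
    dA <- do.call(`[<-`, c(list(dA), sliceIdx(offs[i, ]), list(value = sl)))
  }
  dA
}

layerSpatials <- function(spec) {
  ## spatial extents of each block's input
  sp <- list(spec@patchSize)
  for (l in seq_len(spec@depth - 1L))
    sp[[l + 1L]] <- sp[[l]] %/% 2L
  sp
}

#' Number of trainable parameters of a spec (closed form)
#'
#' \code{C*w*k^dim + w + (d-1)*(w^2*k^dim + w) + w*K + K}: the first conv
#' (+bias), the remaining d-1 convs (+biases), and the affine head. Equals
#' the introspected weight count of [buildModel()].
#'
#' @param spec a [ClassifierSpec-class].
#' @return integer parameter count.
#' @export
countParameters <- function(spec) {
  kv <- spec@kernelExtent^spec@dim
  w <- spec@width
  as.integer(spec@inChannels * w * kv + w +
             (spec@depth - 1L) * (w^2 * kv + w) +
             w * spec@nClasses + spec@nClasses)
}

#' Build a minimalist CNN
#'
#' All weights use fan-in-scaled uniform initialization
#' (\code{U(-1/sqrt(fanin), 1/sqrt(fanin))}, zero biases) drawn from the
#' given seed, so a build is fully deterministic and an untrained model's
#' predictive distribution is close to uniform.
#'
#' @param spec a [ClassifierSpec-class].
#' @param seed RNG seed for initialization.
#' @param patchSettings list(includeMaskChannel, normalization) recorded in
#'   the model so prediction can normalize patches exactly as training did.
#' @return a [MinimalistCNN-class] (callable through [predictLogits()]).
#' @export
buildModel <- function(spec, seed = 0,
                       patchSettings = list(includeMaskChannel = TRUE,
                                            normalization = "minmax")) {
  validObject(spec)
  set.seed(as.integer(seed))
  kv <- spec@kernelExtent^spec@dim
  w <- spec@width
  conv <- vector("list", spec@depth)
  for (l in seq_len(spec@depth)) {
    cin <- if (l == 1L) spec@inChannels else w
    fanin <- cin * kv
    a <- 1 / sqrt(fanin)
    conv[[l]] <- list(W = matrix(stats::runif(w * fanin, -a, a), w, fanin),
                      b = numeric(w))
  }
  a <- 1 / sqrt(w)
  head <- list(V = matrix(stats::runif(spec@nClasses * w, -a, a),
                          spec@nClasses, w),
               c = numeric(spec@nClasses))
  new("MinimalistCNN", spec = spec,
      weights = list(conv = conv, head = head),
      patchSettings = patchSettings)
}

nnForward <- function(model, X, keepCache = FALSE) {
  spec <- model@spec
  nd <- spec@dim
  d <- dim(X)
  if (length(d) != nd + 2L)
    stop("input must be a (C, spatial..., n) array")
  if (d[1L] != spec@inChannels)
    stop(sprintf("channel mismatch: model expects %d input channels, got %d",
                 spec@inChannels, d[1L]))
  if (!all(d[2:(nd + 1L)] == spec@patchSize))
    stop(sprintf("patch size mismatch: model expects %s, got %s",
                 paste(spec@patchSize, collapse = "x"),
                 paste(d[2:(nd + 1L)], collapse = "x")))
  N <- d[length(d)]
  sps <- layerSpatials(spec)
  cache <- if (keepCache) vector("list", spec@depth) else NULL
  A <- X
  for (l in seq_len(spec@depth)) {
    cin <- if (l == 1L) spec@inChannels else spec@width
    plan <- convPlan(cin, sps[[l]], spec@kernelExtent)
    Xc <- im2col(A, plan, N)
    preZ <- model@weights$conv[[l]]$W %*% Xc + model@weights$conv[[l]]$b
    Zr <- pmax(preZ, 0)
    dim(Zr) <- c(spec@width, sps[[l]], N)
    pl <- maxPool2(Zr, nd)
    if (keepCache)
      cache[[l]] <- list(Xc = Xc, preZ = preZ, arg = pl$arg,
                         relu = Zr, plan = plan)
    A <- pl$out
  }
  pooledSp <- dim(A)[2:(nd + 1L)]
  S <- prod(pooledSp)
  m <- A
  dim(m) <- c(spec@width, S, N)
  g <- matrix(0, spec@width, N)
  for (n in seq_len(N)) g[, n] <- rowMeans(m[, , n, drop = FALSE], dims = 1L)
  logits <- model@weights$head$V %*% g + model@weights$head$c
  list(logits = logits, g = g, pooled = A, pooledSp = pooledSp,
       cache = cache, N = N)
}

#' Class logits for a batch of patches
#'
#' @param model a [MinimalistCNN-class].
#' @param x a [PatchSet-class] or a (C, spatial..., n) array.
#' @return matrix (n, K) of logits.
#' @export
predictLogits <- function(model, x) {
  X <- if (is(x, "PatchSet")) x@patches else x
  t(nnForward(model, X)$logits)
}

nnBackward <- function(model, fw, dLogits) {
  spec <- model@spec
  nd <- spec@dim
  N <- fw$N
  w <- spec@width
  grads <- list(conv = vector("list", spec@depth),
                head = list(V = dLogits %*% t(fw$g),
                            c = rowSums(dLogits)))
  dg <- t(model@weights$head$V) %*% dLogits          # (w, N)
  S <- prod(fw$pooledSp)
  dPool <- aperm(array(dg / S, c(w, N, S)), c(1L, 3L, 2L))
  dim(dPool) <- c(w, fw$pooledSp, N)
  dX <- dPool
  sps <- layerSpatials(spec)
  for (l in rev(seq_len(spec@depth))) {
    cc <- fw$cache[[l]]
    dRelu <- maxUnpool2(dX, cc$arg, sps[[l]], nd)
    dim(dRelu) <- c(w, prod(sps[[l]]) * N)
    dPre <- dRelu * (cc$preZ > 0)
    grads$conv[[l]] <- list(W = dPre %*% t(cc$Xc), b = rowSums(dPre))
    if (l > 1L) {
      ## gradient to the layer input = transposed-kernel convolution
      gplan <- convPlan(w, sps[[l]], spec@kernelExtent)
      dim(dPre) <- c(w, sps[[l]], N)
      Zc <- im2col(dPre, gplan, N)
      Wr <- flipWeights(model@weights$conv[[l]]$W, convPlan(
        w, sps[[l]], spec@kernelExtent))
      dXmat <- Wr %*% Zc                              # (w, cols*N)
      dX <- array(dXmat, c(w, sps[[l]], N))
    }
  }
  grads
}

softmaxCols <- function(logits) {
  mx <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, mx))
  sweep(e, 2L, colSums(e), "/")
}

nnLossGrad <- function(model, X, y0, classWeights = NULL) {
  ## y0: 0-based class indices; returns mean cross-entropy, grads, preds
  fw <- nnForward(model, X, keepCache = TRUE)
  P <- softmaxCols(fw$logits)
  N <- fw$N
  sel <- cbind(y0 + 1L, seq_len(N))
  wts <- if (is.null(classWeights)) rep(1, N) else classWeights[y0 + 1L]
  wts <- wts / sum(wts)
  loss <- -sum(wts * log(pmax(P[sel], 1e-12)))
  dLogits <- P
  dLogits[sel] <- dLogits[sel] - 1
  dLogits <- sweep(dLogits, 2L, wts, "*")
  preds <- max.col(t(fw$logits), ties.method = "first")  # smallest index wins
  list(loss = loss, grads = nnBackward(model, fw, dLogits),
       preds = preds - 1L)
}

## flat views of the weights, for Adam and for introspection
flattenWeights <- function(weights) {
  out <- list()
  for (l in seq_along(weights$conv)) {
    out[[paste0("convW", l)]] <- weights$conv[[l]]$W
    out[[paste0("convb", l)]] <- weights$conv[[l]]$b
  }
  out$headV <- weights$head$V
  out$headc <- weights$head$c
  out
}

unflattenWeights <- function(flat, depth) {
  conv <- lapply(seq_len(depth), function(l)
    list(W = flat[[paste0("convW", l)]], b = flat[[paste0("convb", l)]]))
  list(conv = conv, head = list(V = flat$headV, c = flat$headc))
}

#' Introspected trainable-weight count of a built model
#'
#' @param model a [MinimalistCNN-class].
#' @return integer: total length of all weight arrays.
#' @export
introspectParameterCount <- function(model) {
  sum(vapply(flattenWeights(model@weights), length, 0L))
}

#' Save / load a classifier checkpoint
#'
#' A checkpoint is self-describing: \code{<path>.rds} holds the weights,
#' \code{<path>.json} is a sidecar with the architecture spec and the patch
#' settings (size, mask channel, normalization), so prediction can rebuild
#' the exact training-time input pipeline.
#'
#' @param model a [MinimalistCNN-class].
#' @param path base path (extensions are appended).
#' @return \code{saveCheckpoint}: invisibly, the base path.
#' @export
saveCheckpoint <- function(model, path) {
  spec <- model@spec
  saveRDS(model@weights, paste0(path, ".rds"), version = 2L)
  jsonlite::write_json(
    list(spec = list(dim = spec@dim, depth = spec@depth, width = spec@width,
                     in_channels = spec@inChannels, n_classes = spec@nClasses,
                     kernel_extent = spec@kernelExtent,
                     patch_size = I(spec@patchSize)),
         patch = list(include_mask_channel =
                        isTRUE(model@patchSettings$includeMaskChannel),
                      normalization = model@patchSettings$normalization)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint}: the reconstructed [MinimalistCNN-class];
#'   weight shapes inconsistent with the sidecar spec are an error.
#' @export
loadCheckpoint <- function(path) {
  weights <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  sp <- side$spec
  spec <- classifierSpec(dim = sp$dim, depth = sp$depth, width = sp$width,
                         inChannels = sp$in_channels, nClasses = sp$n_classes,
                         kernelExtent = sp$kernel_extent,
                         patchSize = sp$patch_size)
  kv <- spec@kernelExtent^spec@dim
  for (l in seq_len(spec@depth)) {
    cin <- if (l == 1L) spec@inChannels else spec@width
    if (!all(dim(weights$conv[[l]]$W) == c(spec@width, cin * kv)))
      stop("checkpoint weights do not match the sidecar spec (conv block ",
           l, ")")
  }
  if (!all(dim(weights$head$V) == c(spec@nClasses, spec@width)))
    stop("checkpoint weights do not match the sidecar spec (head)")
  new("MinimalistCNN", spec = spec, weights = weights,
      patchSettings = list(
        includeMaskChannel = isTRUE(side$patch$include_mask_channel),
        normalization = side$patch$normalization))
}
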