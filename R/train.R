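#' @include network.R
NULL

## ---------------------------------------------------------------------------
## Augmentation registry: name -> function(patch, params, ndSpatial).
## Patches are (C, Y, X) or (C, Z, Y, X); transforms act on the (Y, X)
## plane and are applied identically to every channel (including the mask
## channel) and every Z slice.
## ---------------------------------------------------------------------------

.augmentRegistry <- new.env(parent = emptyenv())

#' Register a named augmentation transform
#'
#' Extension point for augmentation pipelines beyond the built-ins
#' (\code{hflip}, \code{vflip}, \code{rot90}, \code{rotate}).
#'
#' @param name transform name used in pipelines.
#' @param fn function(patch, params, ndSpatial) returning an array of the
#'   same shape.
#' @return invisibly, \code{name}.
#' @export
registerAugmentation <- function(name, fn) {
  assign(name, fn, envir = .augmentRegistry)
  invisible(name)
}

#' @rdname registerAugmentation
#' @export
knownAugmentations <- function() sort(ls(.augmentRegistry))

reverseAxis <- function(a, axis) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- rev(seq_len(d[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

augHflip <- function(patch, params, nd) reverseAxis(patch, length(dim(patch)))
augVflip <- function(patch, params, nd) reverseAxis(patch, length(dim(patch)) - 1L)

augRot90 <- function(patch, params, nd) {
  d <- dim(patch)
  na <- length(d)
  if (d[na] != d[na - 1L])
    stop("rot90 requires square (Y, X) patch extents")
  perm <- seq_len(na)
  perm[c(na - 1L, na)] <- c(na, na - 1L)
  reverseAxis(aperm(patch, perm), na - 1L)
}

augRotate <- function(patch, params, nd) {
  rng <- if (is.null(params$angle_range)) c(-180, 180)
         else unlist(params$angle_range)
  theta <- stats::runif(1L, rng[1], rng[2]) * pi / 180
  d <- dim(patch)
  na <- length(d)
  H <- d[na - 1L]; W <- d[na]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  ## nearest-neighbor pull-back through the inverse rotation
  sy <- round(cy + cos(theta) * (g$y - cy) - sin(theta) * (g$x - cx))
  sx <- round(cx + sin(theta) * (g$y - cy) + cos(theta) * (g$x - cx))
  ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  M <- prod(d[-c(na - 1L, na)])
  flat <- matrix(patch, M, H * W)
  out <- matrix(0, M, H * W)
  out[, which(ok)] <- flat[, sy[ok] + H * (sx[ok] - 1L)]
  array(out, d)
}

registerAugmentation("hflip", augHflip)
registerAugmentation("vflip", augVflip)
registerAugmentation("rot90", augRot90)
registerAugmentation("rotate", augRotate)

#' Apply an augmentation pipeline to one patch
#'
#' Each transform fires independently with its configured probability
#' (draws come from the current RNG stream, so training runs are
#' reproducible from their seed). The mask channel, when present, is
#' transformed identically to the intensity channels.
#'
#' @param patch (C, spatial...) array.
#' @param pipeline ordered list of \code{list(name=, params=, probability=)}.
#' @return the transformed array (same shape and channel count).
#' @export
augmentPatch <- function(patch, pipeline) {
  nd <- length(dim(patch)) - 1L
  for (step in pipeline) {
    step <- canonicalAugmentation(step)
    fn <- .augmentRegistry[[step$name]]
    if (is.null(fn))
      stop(sprintf("unknown transform '%s'; known: %s", step$name,
                   paste(knownAugmentations(), collapse = ", ")))
    if (step$probability >= 1 || stats::runif(1L) < step$probability)
      patch <- fn(patch, step$params, nd)
  }
  patch
}

#' Stratified train/validation split of a labeled PatchSet
#'
#' Per class, \code{floor(fraction * n_k)} patches go to validation;
#' deterministic given the seed and order-stable (original patch order is
#' preserved within each part).
#'
#' @param patchset a labeled [PatchSet-class].
#' @param fraction validation fraction in [0, 0.5].
#' @param seed RNG seed.
#' @return list(train = PatchSet, val = PatchSet).
#' @export
makeSplits <- function(patchset, fraction, seed) {
  if (fraction < 0 || fraction > 0.5)
    stop("validation fraction must be in [0, 0.5]")
  labels <- patchLabels(patchset)
  if (is.null(labels)) stop("makeSplits needs a labeled PatchSet")
  set.seed(as.integer(seed))
  valIdx <- integer(0)
  for (k in sort(unique(labels))) {
    pos <- which(labels == k)
    nv <- floor(fraction * length(pos))
    if (length(pos) - nv < 1L)
      stop(sprintf("fraction %g would leave class %d empty in train",
                   fraction, k))
    if (nv > 0) valIdx <- c(valIdx, pos[sample.int(length(pos), nv)])
  }
  valIdx <- sort(valIdx)
  trainIdx <- setdiff(seq_along(labels), valIdx)
  list(train = patchset[trainIdx], val = patchset[valIdx])
}

adamInit <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adamStep <- function(flat, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Train a classifier on a labeled PatchSet
#'
#' Minimizes mean cross-entropy over shuffled mini-batches with Adam; the
#' learning rate is multiplied by \code{stepFactor} every \code{stepEvery}
#' epochs. Augmentation draws happen per sample per epoch (online).
#' Fully deterministic given the config seed: initialization is the
#' model's, and sampling, shuffling and augmentation draws all come from
#' one seeded stream.
#'
#' @param model a [MinimalistCNN-class] (its nClasses defines K).
#' @param patchset a labeled [PatchSet-class]; every class 1..K must have
#'   at least one example.
#' @param cfg a [TrainingConfig-class].
#' @param classWeighting "none" (default) or "inverse_frequency" for
#'   imbalanced training sets.
#' @return list(model, history = data.frame(epoch, loss, accuracy),
#'   valAccuracy = numeric or NA). The history accuracy is the running
#'   training accuracy (predictions taken just before each update).
#' @export
trainClassifier <- function(model, patchset, cfg,
                            classWeighting = c("none", "inverse_frequency")) {
  classWeighting <- match.arg(classWeighting)
  spec <- model@spec
  K <- spec@nClasses
  labels <- patchLabels(patchset)
  if (is.null(labels) || nObjects(patchset) == 0L)
    stop("training needs a labeled, non-empty PatchSet")
  if (any(labels > K))
    stop(sprintf("label %d exceeds the declared number of classes (%d)",
                 max(labels), K))
  val <- NULL
  if (cfg@validationFraction > 0) {
    sp <- makeSplits(patchset, cfg@validationFraction, cfg@seed)
    patchset <- sp$train
    val <- sp$val
    labels <- patchLabels(patchset)
  }
  counts <- tabulate(labels, nbins = K)
  if (any(counts == 0L))
    stop("class(es) with 0 training examples: ",
         paste(which(counts == 0L), collapse = ", "))
  classWeights <- if (classWeighting == "inverse_frequency")
    sum(counts) / (K * counts) else NULL

  nd <- spec@dim
  n <- nObjects(patchset)
  X <- patchset@patches
  y0 <- labels - 1L
  flat <- flattenWeights(model@weights)
  state <- adamInit(flat)
  hasAug <- length(cfg@augmentation) > 0
  history <- data.frame(epoch = seq_len(cfg@epochs), loss = NA_real_,
                        accuracy = NA_real_)
  set.seed(cfg@seed)
  sliceIdx <- function(i) c(rep(list(quote(expr = )), nd + 1L), list(i))
  for (e in seq_len(cfg@epochs)) {
    lr <- cfg@learningRate * cfg@stepFactor^((e - 1L) %/% cfg@stepEvery)
    perm <- sample.int(n)
    lossSum <- 0
    correct <- 0L
    for (start in seq.int(1L, n, by = cfg@batchSize)) {
      idx <- perm[start:min(start + cfg@batchSize - 1L, n)]
      Xb <- do.call(`[`, c(list(X), sliceIdx(idx), list(drop = FALSE)))
      if (hasAug) {
        for (i in seq_along(idx)) {
          p <- do.call(`[`, c(list(Xb), sliceIdx(i), list(drop = FALSE)))
          dim(p) <- dim(Xb)[seq_len(nd + 1L)]
          p <- augmentPatch(p, cfg@augmentation)
          Xb <- do.call(`[<-`, c(list(Xb), sliceIdx(i), list(value = p)))
        }
      }
      model@weights <- unflattenWeights(flat, spec@depth)
      lg <- nnLossGrad(model, Xb, y0[idx], classWeights)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", e)
      lossSum <- lossSum + lg$loss * length(idx)
      correct <- correct + sum(lg$preds == y0[idx])
      upd <- adamStep(flat, flattenWeights(lg$grads), state, lr,
                      cfg@beta1, cfg@beta2)
      flat <- upd$flat
      state <- upd$state
    }
    history$loss[e] <- lossSum / n
    history$accuracy[e] <- correct / n
  }
  model@weights <- unflattenWeights(flat, spec@depth)
  valAccuracy <- NA_real_
  if (!is.null(val) && nObjects(val) > 0L) {
    logits <- predictLogits(model, val)
    pred <- max.col(logits, ties.method = "first")
    valAccuracy <- mean(pred == patchLabels(val))
  }
  list(model = model, history = history, valAccuracy = valAccuracy)
}
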