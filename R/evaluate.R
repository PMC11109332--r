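#' @include predict.R
NULL

#' One-vs-rest confusion counts per class
#'
#' For every class i: \code{n_i} (true element count), and TP/FP/FN/TN
#' obtained by binarizing the multi-class outcome against class i. Truth
#' and prediction must cover exactly the same objects.
#'
#' @param truth named integer vector (object id -> class) or an
#'   [AnnotationSet-class].
#' @param table prediction data.frame (image_id, object_id, class).
#' @param nClasses number of classes N (default: max class seen).
#' @return data.frame(class, n, TP, FP, FN, TN).
#' @export
confusionCounts <- function(truth, table, nClasses = NULL) {
  if (is(truth, "AnnotationSet")) {
    r <- annotations(truth)
    truth <- structure(r$class, names = r$object_id)
  }
  tv <- truth[as.character(table$object_id)]
  if (anyNA(tv))
    stop("object(s) in prediction missing from truth: ",
         paste(table$object_id[is.na(tv)], collapse = ", "))
  if (length(truth) != nrow(table))
    stop("object(s) in truth missing from prediction: ",
         paste(setdiff(names(truth), as.character(table$object_id)),
               collapse = ", "))
  pv <- table$class
  if (is.null(nClasses)) nClasses <- max(tv, pv)
  total <- length(tv)
  out <- data.frame(class = seq_len(nClasses), n = 0L, TP = 0L, FP = 0L,
                    FN = 0L, TN = 0L)
  for (i in seq_len(nClasses)) {
    tp <- sum(tv == i & pv == i)
    fp <- sum(tv != i & pv == i)
    fn <- sum(tv == i & pv != i)
    out[i, c("n", "TP", "FP", "FN", "TN")] <-
      c(sum(tv == i), tp, fp, fn, total - tp - fp - fn)
  }
  out
}

#' Aggregate metrics from per-class confusion counts
#'
#' Implements the as-printed weighted forms
#' \deqn{Precision = (1/N) \sum_i n_i TP_i / (n_i TP_i + FP_i)}
#' \deqn{Recall = (1/N) \sum_i n_i TP_i / (n_i TP_i + FN_i)}
#' \deqn{F1 = 2 Precision \cdot Recall / (Precision + Recall)}
#' \deqn{Accuracy = (1/N) \sum_i (TP_i + TN_i) / (TP_i + FP_i + TN_i + FN_i)}
#' with N = number of classes. Note the class-size weighting sits inside
#' the per-class fractions, which differs from the conventional
#' support-weighted mean; the conventional support-weighted precision,
#' recall and F1 (and the plain fraction-correct accuracy) are computed
#' alongside for interoperability. A zero-denominator term contributes 0
#' and raises a warning.
#'
#' @param counts data.frame from [confusionCounts()].
#' @return a [MetricsReport-class].
#' @export
metricsAsPrinted <- function(counts) {
  N <- nrow(counts)
  safeDiv <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning("zero denominator in ", what, " for class(es) ",
              paste(counts$class[bad], collapse = ", "),
              "; term(s) set to 0")
    out <- ifelse(bad, 0, num / den)
    out
  }
  precTerms <- safeDiv(counts$n * counts$TP, counts$n * counts$TP + counts$FP,
                       "precision")
  recTerms <- safeDiv(counts$n * counts$TP, counts$n * counts$TP + counts$FN,
                      "recall")
  accTerms <- safeDiv(counts$TP + counts$TN,
                      counts$TP + counts$FP + counts$TN + counts$FN,
                      "accuracy")
  precision <- mean(precTerms)
  recall <- mean(recTerms)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- mean(accTerms)

  ## conventional support-weighted variants
  wts <- counts$n / sum(counts$n)
  pC <- safeDiv(counts$TP, counts$TP + counts$FP, "standard precision")
  rC <- safeDiv(counts$TP, counts$TP + counts$FN, "standard recall")
  fC <- ifelse(pC + rC == 0, 0, 2 * pC * rC / (pC + rC))
  weighted <- c(precision = sum(wts * pC), recall = sum(wts * rC),
                f1 = sum(wts * fC),
                accuracy = sum(counts$TP) / sum(counts$n))
  new("MetricsReport", perClass = counts,
      asPrinted = c(precision = precision, recall = recall, f1 = f1,
                    accuracy = accuracy),
      weighted = weighted, nClasses = as.integer(N))
}

#' Grad-CAM class activation map for one patch
#'
#' Channel weights are the spatial average of the gradient of the target
#' class logit with respect to the last convolution block's (post-ReLU)
#' activations; the map is the rectified weighted sum of those activation
#' channels, upsampled to the patch's spatial size (nearest-neighbor by
#' default). Because only one logit is differentiated, the map is
#' invariant to adding a constant to all logits.
#'
#' @param model a [MinimalistCNN-class].
#' @param patch (C, spatial...) array, normalized as at training time.
#' @param targetClass class index in 1..K.
#' @param upsample "nearest" or "linear".
#' @return a [Heatmap-class] with raw and [0,1]-rescaled views.
#' @export
gradCAM <- function(model, patch, targetClass,
                    upsample = c("nearest", "linear")) {
  upsample <- match.arg(upsample)
  spec <- model@spec
  if (targetClass < 1 || targetClass > spec@nClasses)
    stop("target class out of range 1..", spec@nClasses)
  nd <- spec@dim
  X <- array(patch, c(dim(patch), 1L))
  fw <- nnForward(model, X, keepCache = TRUE)
  w <- spec@width
  ## d(logit_c)/d(pooled[j, pos]) = V[c, j] / S_gap; route through the pool
  S <- prod(fw$pooledSp)
  v <- model@weights$head$V[targetClass, ]
  dPool <- aperm(array(v / S, c(w, 1L, S)), c(1L, 3L, 2L))
  dim(dPool) <- c(w, fw$pooledSp, 1L)
  last <- spec@depth
  spLast <- layerSpatials(spec)[[last]]
  dA <- maxUnpool2(dPool, fw$cache[[last]]$arg, spLast, nd)
  A <- fw$cache[[last]]$relu                      # (w, spatial..., 1)
  dim(dA) <- c(w, prod(spLast))
  dim(A) <- c(w, prod(spLast))
  alpha <- rowMeans(dA)                           # spatial mean of gradients
  raw <- pmax(colSums(A * alpha), 0)
  dim(raw) <- spLast
  raw <- upsampleArray(raw, spec@patchSize, upsample)
  hi <- max(raw)
  rescaled <- if (hi > 0) raw / hi else raw
  new("Heatmap", raw = raw, rescaled = rescaled,
      targetClass = as.integer(targetClass))
}

upsampleArray <- function(a, target, mode) {
  d <- dim(a)
  if (all(d == target)) return(a)
  grids <- lapply(seq_along(d), function(ax) {
    ## map target coordinates onto source coordinates (align centers)
    (seq_len(target[ax]) - 0.5) * d[ax] / target[ax] + 0.5
  })
  if (mode == "nearest") {
    idx <- lapply(seq_along(d), function(ax)
      pmin(pmax(round(grids[[ax]]), 1L), d[ax]))
    return(do.call(`[`, c(list(a), idx)))
  }
  ## separable linear interpolation
  out <- a
  for (ax in seq_along(d)) {
    dd <- dim(out)
    g <- grids[[ax]]
    lo <- pmin(pmax(floor(g), 1L), dd[ax])
    hi <- pmin(lo + 1L, dd[ax])
    fr <- pmin(pmax(g - lo, 0), 1)
    perm <- c(ax, seq_along(dd)[-ax])
    m <- aperm(out, perm)
    dim(m) <- c(dd[ax], prod(dd[-ax]))
    m2 <- m[lo, , drop = FALSE] * (1 - fr) + m[hi, , drop = FALSE] * fr
    dim(m2) <- c(length(g), dd[perm[-1L]])
    out <- aperm(m2, order(perm))
  }
  out
}

#' Coefficient of determination between predicted and manual counts
#'
#' Standard R-squared of the predicted counts against the manually measured
#' counts, taken about the identity line:
#' \code{1 - sum((pred - manual)^2) / sum((manual - mean(manual))^2)}.
#'
#' @param predCounts,manualCounts numeric vectors (one entry per image or
#'   per condition; at least 2).
#' @return R-squared (1 for identical vectors; can be negative when the
#'   predictions are worse than the manual mean).
#' @export
countConcordance <- function(predCounts, manualCounts) {
  if (length(predCounts) != length(manualCounts))
    stop("count vectors must have equal length")
  if (length(manualCounts) < 2L)
    stop("need at least 2 paired counts")
  sst <- sum((manualCounts - mean(manualCounts))^2)
  if (sst == 0)
    stop("manual counts are constant: R^2 is undefined")
  1 - sum((predCounts - manualCounts)^2) / sst
}
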