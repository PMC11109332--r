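# brute-force oracle: per-class one-vs-rest counts by an explicit double loop
bruteConfusion <- function(tv, pv, K) {
  out <- data.frame(class = seq_len(K), n = 0L, TP = 0L, FP = 0L, FN = 0L,
                    TN = 0L)
  for (i in seq_len(K)) {
    for (j in seq_along(tv)) {
      isI <- tv[j] == i
      saidI <- pv[j] == i
      if (isI) out$n[i] <- out$n[i] + 1L
      if (isI && saidI) out$TP[i] <- out$TP[i] + 1L
      if (!isI && saidI) out$FP[i] <- out$FP[i] + 1L
      if (isI && !saidI) out$FN[i] <- out$FN[i] + 1L
      if (!isI && !saidI) out$TN[i] <- out$TN[i] + 1L
    }
  }
  out
}

asTable <- function(pv) data.frame(image_id = "im",
                                   object_id = seq_along(pv),
                                   class = pv, confidence = 1)

test_that("confusionCounts equals the brute-force double loop", {
  set.seed(21)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    n <- sample(10:300, 1)
    tv <- sample(seq_len(K), n, replace = TRUE)
    pv <- sample(seq_len(K), n, replace = TRUE)
    truth <- structure(tv, names = seq_len(n))
    got <- confusionCounts(truth, asTable(pv), nClasses = K)
    expect_identical(got, bruteConfusion(tv, pv, K))
  }
  # invariants: TP + FN = n; four counts partition the objects
  tv <- sample(1:3, 60, replace = TRUE)
  pv <- sample(1:3, 60, replace = TRUE)
  cc <- confusionCounts(structure(tv, names = 1:60), asTable(pv))
  expect_identical(cc$TP + cc$FN, cc$n)
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 60L))
  # coverage mismatches are errors
  expect_error(confusionCounts(structure(tv[-1], names = 2:60), asTable(pv)),
               "missing")
})

test_that("metrics match the hand-derived two-class case exactly", {
  # confusion [[8,2],[1,9]]: class1 (TP,FP,FN,TN)=(8,1,2,9); class2 (9,2,1,8)
  tv <- c(rep(1L, 10), rep(2L, 10))
  pv <- c(rep(1L, 8), 2L, 2L, 1L, rep(2L, 9))
  cc <- confusionCounts(structure(tv, names = 1:20), asTable(pv))
  expect_identical(cc$TP, c(8L, 9L))
  expect_identical(cc$FP, c(1L, 2L))
  expect_identical(cc$FN, c(2L, 1L))
  expect_identical(cc$TN, c(9L, 8L))
  rep_ <- metricsAsPrinted(cc)
  prec <- (80 / 81 + 90 / 92) / 2
  rec <- (80 / 82 + 90 / 91) / 2
  expect_equal(unname(rep_@asPrinted["precision"]), prec, tolerance = 1e-15)
  expect_equal(unname(rep_@asPrinted["recall"]), rec, tolerance = 1e-15)
  expect_equal(unname(rep_@asPrinted["f1"]), 2 * prec * rec / (prec + rec),
               tolerance = 1e-15)
  expect_equal(unname(rep_@asPrinted["accuracy"]), 0.85, tolerance = 1e-15)
  # the printed and conventional weighted forms differ measurably here
  expect_gt(abs(rep_@asPrinted["precision"] - rep_@weighted["precision"]),
            0.01)
})

test_that("metrics degenerate cases: perfect, trivial and empty classes", {
  # perfect classifier: everything is 1
  tv <- rep(1:3, each = 5)
  cc <- confusionCounts(structure(tv, names = 1:15), asTable(tv))
  rep_ <- metricsAsPrinted(cc)
  expect_equal(unname(rep_@asPrinted), rep(1, 4), tolerance = 1e-15)
  expect_equal(unname(rep_@weighted), rep(1, 4), tolerance = 1e-15)

  # all predictions class 1 on balanced 2-class data: printed accuracy 0.5
  tv <- rep(1:2, each = 10)
  cc <- confusionCounts(structure(tv, names = 1:20),
                        asTable(rep(1L, 20)))
  warns <- capture_warnings(rep_ <- metricsAsPrinted(cc))
  expect_true(all(grepl("zero denominator", warns)))
  expect_equal(unname(rep_@asPrinted["accuracy"]), 0.5, tolerance = 1e-15)
})

test_that("Grad-CAM matches the analytic single-filter toy network", {
  # depth 1, width 1: map = ReLU((v/S) * A), S = spatial size of A
  spec <- classifierSpec(2, 1, 1, 1, 2, 3, 6)
  m <- buildModel(spec, seed = 3)
  patch <- array(runif(36), c(1, 6, 6))
  # independent conv oracle: direct loops over the 3x3 window
  W <- array(m@weights$conv[[1]]$W[1, ], c(1, 3, 3))
  b <- m@weights$conv[[1]]$b[1]
  A <- matrix(0, 6, 6)
  for (y in 1:6) for (x in 1:6) {
    acc <- b
    for (ky in 1:3) for (kx in 1:3) {
      sy <- y + ky - 2; sx <- x + kx - 2
      if (sy >= 1 && sy <= 6 && sx >= 1 && sx <= 6)
        acc <- acc + W[1, ky, kx] * patch[1, sy, sx]
    }
    A[y, x] <- max(acc, 0)
  }
  for (target in 1:2) {
    v <- m@weights$head$V[target, 1]
    expected <- pmax(v / 36 * A, 0)
    hm <- gradCAM(m, patch, target)
    expect_equal(hm@raw, expected, tolerance = 1e-12)
    expect_true(all(hm@raw >= 0))
  }

  # zero head row -> zero map (and the rescaled view stays zero)
  m0 <- m
  m0@weights$head$V[1, ] <- 0
  hm0 <- gradCAM(m0, patch, 1)
  expect_true(all(hm0@raw == 0))
  expect_true(all(hm0@rescaled == 0))

  # adding a constant to all logits leaves the map unchanged
  mshift <- m
  mshift@weights$head$c <- mshift@weights$head$c + 5
  expect_equal(gradCAM(mshift, patch, 2)@raw, gradCAM(m, patch, 2)@raw,
               tolerance = 1e-12)

  expect_error(gradCAM(m, patch, 3), "range")
})

test_that("Grad-CAM maps upsample to the patch size and stay non-negative", {
  spec <- tinySpec2d(inChannels = 1, patchSize = 16)
  m <- buildModel(spec, seed = 6)
  patch <- array(runif(256), c(1, 16, 16))
  hm <- gradCAM(m, patch, 1)
  expect_identical(dim(hm@raw), c(16L, 16L))
  expect_true(all(hm@raw >= 0))
  expect_true(max(hm@rescaled) <= 1)
  hml <- gradCAM(m, patch, 1, upsample = "linear")
  expect_identical(dim(hml@raw), c(16L, 16L))
  expect_true(all(hml@raw >= 0))
})

test_that("count concordance follows the identity-line definition", {
  expect_equal(countConcordance(c(3, 7, 11), c(3, 7, 11)), 1)
  # (1,2,3) manual vs (2,4,6) predicted: 1 - 14/2 = -6
  expect_equal(countConcordance(c(2, 4, 6), c(1, 2, 3)), -6)
  expect_error(countConcordance(c(1, 2), c(5, 5)), "constant")
  expect_error(countConcordance(1, 1), "at least 2")
})
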