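test_that("PCA matches an independent eigendecomposition oracle up to sign", {
  set.seed(11)
  X <- matrix(rnorm(100 * 32), 100, 32)
  fm <- pcaTransform(X)
  sc <- featureValues(fm)
  # oracle: direct eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(cov(Xc), symmetric = TRUE)
  oracle <- Xc %*% eg$vectors
  for (j in 1:10) {
    agree <- max(abs(sc[, j] - oracle[, j]))
    flip <- max(abs(sc[, j] + oracle[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  # per-column variance equals the eigenvalue, in decreasing order
  v <- unname(apply(sc, 2, var))
  expect_equal(v[1:10], eg$values[1:10], tolerance = 1e-8)
  expect_true(all(diff(v) <= 1e-8 * v[1]))
  # scores are uncorrelated
  cc <- cov(sc[, 1:10])
  expect_lt(max(abs(cc[upper.tri(cc)])) / cc[1, 1], 1e-8)
  # loadings orthonormal; total variance conserved
  A <- fm@methodParams$loadings
  expect_equal(crossprod(A), diag(ncol(A)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(v), sum(apply(Xc, 2, var)), tolerance = 1e-8)
})

test_that("collinear data put all variance on PC1", {
  t <- seq(0, 1, length.out = 50)
  X <- cbind(t, 2 * t)
  fm <- pcaTransform(X)
  v <- apply(featureValues(fm), 2, var)
  expect_gt(v[1], 0)
  expect_equal(unname(v[2]), 0, tolerance = 1e-12)
  expect_true(featureInfo(fm)$zeroVariance[2])
})

test_that("Haar transform matches the hand-computed example", {
  fm <- haarWd(matrix(c(1, 1, -1, -1), 1), levels = 2)
  v <- as.numeric(featureValues(fm))
  # details level 1 both 0; level-2 detail 2; approximation 0
  expect_equal(v, c(0, 0, 2, 0), tolerance = 1e-12)
})

test_that("Haar transform conserves energy and reconstructs exactly", {
  set.seed(22)
  X <- matrix(rnorm(50 * 64), 50, 64)
  fm <- haarWd(X, levels = 4)
  expect_identical(ncol(featureValues(fm)), 64L)
  expect_lt(max(abs(rowSums(featureValues(fm)^2) - rowSums(X^2))) /
              max(rowSums(X^2)), 1e-9)
  expect_lt(max(abs(haarReconstruct(fm) - X)), 1e-10)
  # constant waveform: all detail coefficients zero
  fc <- haarWd(matrix(3, 1, 64), levels = 4)
  info <- featureInfo(fc)
  details <- grepl("\\.d", info$id)
  expect_equal(as.numeric(featureValues(fc))[details], rep(0, sum(details)),
               tolerance = 1e-12)
  expect_equal(sum(featureValues(fc)^2), 64 * 9, tolerance = 1e-9)
})

test_that("multichannel decomposition equals per-channel decompositions concatenated", {
  set.seed(33)
  A <- matrix(rnorm(10 * 32), 10, 32)
  B <- matrix(rnorm(10 * 32), 10, 32)
  both <- haarWd(cbind(A, B), levels = 4, nChannels = 2)
  sep <- cbind(featureValues(haarWd(A, 4)), featureValues(haarWd(B, 4)))
  expect_equal(unname(featureValues(both)), unname(sep), tolerance = 1e-12)
  expect_identical(featureInfo(both)$channel, rep(1:2, each = 32L))
})

test_that("non-dyadic lengths are padded and flagged", {
  set.seed(44)
  X <- matrix(rnorm(5 * 60), 5, 60)
  fm <- haarWd(X, levels = 4)
  expect_identical(ncol(featureValues(fm)), 64L)
  expect_true(any(featureInfo(fm)$padded))
  expect_lt(max(abs(haarReconstruct(fm) - X)), 1e-10)
})

test_that("equal-weight wPCA equals PCA of the z-scored coefficients", {
  set.seed(55)
  X <- matrix(rnorm(200 * 16), 200, 16)
  w <- rep(2.5, 16)
  wp <- weightedPca(X, w)
  pc <- pcaTransform(scale(X))
  expect_equal(unname(featureValues(wp) / 2.5), unname(featureValues(pc)),
               tolerance = 1e-8)
})

test_that("a dominant weight aligns PC1 with that coefficient", {
  set.seed(66)
  X <- matrix(rnorm(300 * 8), 300, 8)
  w <- c(100, rep(1, 7))
  wp <- weightedPca(X, w)
  z1 <- scale(X)[, 1]
  alignment <- abs(cor(featureValues(wp)[, 1], z1))
  expect_gt(alignment, 0.99)
})

test_that("wPCA validates weights and drops zero-variance columns", {
  X <- cbind(matrix(rnorm(100 * 3), 100, 3), 0)
  expect_error(weightedPca(X, rep(0, 4)), "no informative")
  expect_error(weightedPca(X, c(1, 2)), "one weight per")
  expect_message(wp <- weightedPca(X, rep(1, 4)), "zero-variance")
  expect_identical(wp@methodParams$keptColumns, 1:3)
})

test_that("permuting coefficient columns with their weights permutes nothing in score geometry", {
  set.seed(77)
  X <- matrix(rnorm(150 * 10), 150, 10)
  w <- runif(10, 0.5, 2)
  perm <- sample(10)
  a <- featureValues(weightedPca(X, w))
  b <- featureValues(weightedPca(X[, perm], w[perm]))
  for (j in 1:5) {
    expect_lt(min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j]))), 1e-8)
  }
})
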