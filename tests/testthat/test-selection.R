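test_that("peaks and inflections of a single Gaussian sit where calculus says", {
  m <- manualModel(1, 0, 1)
  pi <- peaksAndInflections(m, c(-5, 5))
  expect_identical(length(pi$grid), 100L)
  expect_equal(range(pi$grid), c(-5, 5))
  expect_identical(length(pi$peaks), 1L)
  expect_lt(abs(pi$peaks), 0.11) # grid step is ~0.1
  expect_identical(length(pi$inflections), 2L)
  expect_lt(max(abs(sort(pi$inflections) - c(-1, 1))), 0.11)
})

test_that("a well-separated two-mode mixture shows 2 peaks and 4 inflections", {
  m <- manualModel(c(0.5, 0.5), c(-4, 4), c(1, 1))
  pi <- peaksAndInflections(m, c(-8, 8))
  expect_identical(length(pi$peaks), 2L)
  expect_identical(length(pi$inflections), 4L)
  # dense-grid oracle agrees on peak locations
  dense <- seq(-8, 8, length.out = 1e5)
  p <- modelDensity(m, dense)
  d1 <- diff(p)
  oracle <- dense[which(d1[-1] < 0 & d1[-length(d1)] > 0) + 1L]
  expect_equal(sort(pi$peaks), sort(oracle), tolerance = 0.2)
})

test_that("iPeak and iInf match closed-form values", {
  single <- manualModel(1, 0, 1)
  expect_equal(iPeak(single, dataRange = c(-5, 5)), 1, tolerance = 1e-3)
  # inflections of N(0,1) at +-1: density ratio 2 exp(-1/2)
  expect_equal(iInf(single, dataRange = c(-5, 5)), 2 * exp(-0.5),
               tolerance = 0.01)
  twin <- manualModel(c(0.5, 0.5), c(-6, 6), c(1, 1))
  expect_equal(iPeak(twin, dataRange = c(-10, 10)), 2, tolerance = 0.01)
})

test_that("iDist matches hand arithmetic and is scale-homogeneous", {
  expect_equal(iDist(manualModel(c(0.5, 0.5), c(0, 2), c(1, 1))), 1)
  # coincident means give zero no matter the weights/scales
  expect_equal(iDist(manualModel(c(0.3, 0.7), c(1, 1), c(0.5, 2))), 0)
  # scaling both sigmas by c scales D by 1/c^2 (means fixed)
  a <- iDist(manualModel(c(0.4, 0.6), c(0, 3), c(1, 2)))
  b <- iDist(manualModel(c(0.4, 0.6), c(0, 3), 2 * c(1, 2)))
  expect_equal(b, a / 4, tolerance = 1e-12)
  # median aggregation over all pairs
  m3 <- manualModel(c(1, 1, 1) / 3, c(0, 1, 5), c(1, 1, 1))
  D <- c(1, 5, 4) / 3
  expect_equal(iDist(m3), median(D), tolerance = 1e-12)
})

test_that("iDist separates bimodal from unimodal features and tracks separation", {
  set.seed(88)
  n <- 3000
  bimodal <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  unimodal <- rnorm(n)
  sc <- scoreFeatures(cbind(bimodal, unimodal), "i_dist", quickOpts(4), k = 8)
  s <- separabilityScores(sc)
  expect_gt(s[1], s[2])
})

test_that("GMM scores are shift-invariant exactly and scale as 1/a under x -> a x", {
  set.seed(99)
  x <- c(rnorm(1500, -2), rnorm(1500, 2))
  a0 <- iDist(fitGmm(x, 8, quickOpts(seed = 3)))
  # pure shift: the EM trajectory is exactly equivariant, D_ij unchanged
  b <- iDist(fitGmm(x + 7, 8, quickOpts(seed = 3)))
  expect_equal(b, a0, tolerance = 1e-8)
  # pure scale: |mu_i - mu_j| scales by a, sigma_i sigma_j by a^2; the
  # relative-log-likelihood stopping rule fires at a slightly different
  # cycle under scaling, so agreement is up to fit noise
  d <- iDist(fitGmm(5 * x, 8, quickOpts(seed = 3)))
  expect_equal(d, a0 / 5, tolerance = 0.2 * a0)
  # i_peak, by contrast, is affine-invariant (up to the same fit noise)
  p0 <- iPeak(fitGmm(x, 8, quickOpts(seed = 3)), dataRange = range(x))
  p1 <- iPeak(fitGmm(5 * x + 7, 8, quickOpts(seed = 3)),
              dataRange = range(5 * x + 7))
  expect_equal(p1, p0, tolerance = 0.05)
})

test_that("variance metric reproduces classical top-variance PCA selection", {
  set.seed(111)
  X <- matrix(rnorm(300 * 20), 300, 20) %*% diag(seq(3, 0.5, length.out = 20))
  pcs <- pcaTransform(X)
  sc <- scoreFeatures(pcs, "var")
  expect_identical(selectTop(sc, 5L), 1:5)
  # standardized columns all score 1
  sc1 <- scoreFeatures(scale(X), "var")
  expect_equal(unname(separabilityScores(sc1)), rep(1, 20), tolerance = 1e-9)
})

test_that("selectTop ranks correctly with deterministic tie-breaking", {
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_identical(selectTop(s, 5L), c(6L, 8L, 5L, 3L, 1L))
  expect_identical(selectTop(rep(2, 8), 5L), 1:5)
  expect_identical(selectTop(s, 8L), order(-s, seq_along(s)))
  expect_error(selectTop(s, 9L), "exceeds")
  expect_warning(sel <- selectTop(c(1, 0, 0, 0, 0, 2), 5L), "informative")
  expect_identical(sel, c(6L, 1L))
})

test_that("degenerate feature columns score 0 with a warning and are never selected", {
  set.seed(122)
  X <- cbind(rnorm(500), rep(1, 500), c(rnorm(250, -3), rnorm(250, 3)))
  expect_warning(sc <- scoreFeatures(X, "i_dist", quickOpts(5)), "degenerate")
  s <- separabilityScores(sc)
  expect_identical(s[2], 0)
  expect_identical(selectTop(sc, 2L), c(3L, 1L))
})
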