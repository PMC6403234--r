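test_that("single-Gaussian fit recovers the sample moments exactly", {
  set.seed(101)
  x <- rnorm(10000)
  m <- fitGmm(x, 1, fitOptions(nReplicates = 1, covarianceFloor = 0,
                               relTol = 1e-10, seed = 1))
  n <- length(x)
  expect_equal(mixtureMeans(m)[1, 1], mean(x), tolerance = 1e-9)
  # EM's MLE variance uses the 1/n denominator
  expect_equal(mixtureCovariances(m)[1, 1, 1], var(x) * (n - 1) / n,
               tolerance = 1e-9)
  expect_equal(mixtureWeights(m), 1)
})

test_that("well-separated two-component mixture is recovered within CLT tolerance", {
  set.seed(202)
  x <- c(rnorm(2500, -4), rnorm(2500, 4))
  m <- fitGmm(x, 2, fitOptions(seed = 7))
  mu <- sort(mixtureMeans(m)[, 1])
  expect_lt(abs(mu[1] + 4), 0.1)
  expect_lt(abs(mu[2] - 4), 0.1)
  expect_lt(max(abs(mixtureWeights(m) - 0.5)), 0.05)
  expect_true(isConverged(m))
})

test_that("log-likelihood is non-decreasing within a replicate and maximal across replicates", {
  set.seed(303)
  x <- matrix(c(rnorm(400, -3), rnorm(400, 3), rnorm(800)), ncol = 2)
  m <- fitGmm(x, 3, fitOptions(seed = 5))
  tr <- m@logLikTrace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-7 * abs(tr[-1])))
  expect_equal(m@logLik, max(m@diagnostics$replicateLogLik))
  # rerunning with the same options reproduces the same replicates
  m2 <- fitGmm(x, 3, fitOptions(seed = 5))
  expect_identical(m@diagnostics$replicateLogLik,
                   m2@diagnostics$replicateLogLik)
})

test_that("fitGmm validates its inputs", {
  expect_error(fitGmm(rnorm(3), 5, quickOpts()), "at least as many")
  expect_error(fitGmm(c(1, NA, 2), 1, quickOpts()), "non-finite")
  expect_error(fitGmm(rep(2, 50), 2, quickOpts()), "identical")
})

test_that("fixed-mean EM preserves the means bit-exactly and recovers scales", {
  set.seed(404)
  x <- c(rnorm(2000, -3, 0.7), rnorm(2000, 3, 1.3))
  mu <- c(-3, 3)
  m <- fitGmmFixedMeans(x, mu, fitOptions(seed = 2))
  expect_identical(as.numeric(mixtureMeans(m)), mu)
  sds <- sqrt(mixtureCovariances(m)[1, 1, ])
  expect_lt(abs(sds[1] - 0.7), 0.05)
  expect_lt(abs(sds[2] - 1.3), 0.05)
  expect_lt(max(abs(mixtureWeights(m) - 0.5)), 0.03)
  tr <- m@logLikTrace
  expect_true(all(diff(tr) >= -1e-7 * abs(tr[-1])))
})

test_that("fixed-mean EM keeps empty components alive at the floor", {
  set.seed(505)
  x <- rnorm(500)
  # second center far outside the data: captures essentially no mass
  expect_warning(
    m <- fitGmmFixedMeans(x, c(0, 500), fitOptions(nReplicates = 1, seed = 1)),
    "no posterior mass"
  )
  expect_identical(nComponents(m), 2L)
  expect_identical(as.numeric(mixtureMeans(m)), c(0, 500))
  expect_lt(mixtureWeights(m)[2], 1e-6)
})

test_that("mixture density matches closed forms and integrates to 1", {
  m <- manualModel(1, 0, 1)
  expect_equal(modelDensity(m, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  m2 <- manualModel(c(0.5, 0.5), c(-1, 1), c(1, 1))
  expect_equal(modelDensity(m2, 0), dnorm(1), tolerance = 1e-12)
  # quadrature over +-10 SD on a fitted model
  set.seed(606)
  fit <- fitGmm(c(rnorm(1500), rnorm(1500, 6)), 3, quickOpts(3))
  grid <- seq(-10, 16, length.out = 20001)
  integral <- sum(modelDensity(fit, grid)) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-6)
})

test_that("posterior responsibilities are proper and match symmetry cases", {
  m <- manualModel(c(0.5, 0.5), c(-4, 4), c(1, 1))
  r <- posteriorResponsibilities(m, c(-4, 0, 4))
  expect_equal(rowSums(r), rep(1, 3), tolerance = 1e-12)
  expect_gt(r[1, 1], 0.99)
  expect_equal(r[2, ], c(0.5, 0.5), tolerance = 1e-12)
  expect_gt(r[3, 2], 0.99)
  one <- manualModel(1, 0, 1)
  expect_equal(posteriorResponsibilities(one, rnorm(5))[, 1], rep(1, 5))
})

test_that("dimension mismatches are rejected", {
  m <- manualModelMv(c(0.5, 0.5), matrix(0, 2, 3),
                     array(diag(3), c(3, 3, 2)))
  expect_error(modelDensity(m, matrix(0, 1, 2)), "dimensionality")
  expect_error(posteriorResponsibilities(m, matrix(0, 1, 5)), "dimensionality")
})

test_that("fits agree with an independent mixture implementation on easy data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust)) # Mclust needs its namespace attached
  set.seed(707)
  x <- c(rnorm(1500, -3, 0.8), rnorm(1500, 3, 1.2))
  mine <- fitGmm(x, 2, fitOptions(seed = 9))
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(mixtureMeans(mine)[, 1]) -
                      sort(ref$parameters$mean))), 0.05)
  expect_lt(abs(mine@logLik - ref$loglik), 1e-3 * abs(ref$loglik))
  expect_lt(max(abs(sort(mixtureWeights(mine)) -
                      sort(ref$parameters$pro))), 0.02)
})
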