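test_that("overclustering cannot fall below the likelihood of a small fit", {
  d <- threeClusterData(150, sep = 7, seed = 5)
  big <- overcluster(d$X, 12, quickOpts(9, nReplicates = 5))
  small <- fitGmm(d$X, 3, quickOpts(9, nReplicates = 5))
  expect_gte(big@logLik, small@logLik - 1e-6 * abs(small@logLik))
  expect_identical(nComponents(big), 12L)
})

test_that("near-coincident components merge into a single peak", {
  set.seed(14)
  k <- 12
  centers <- matrix(rnorm(k * 2, sd = 0.005), k, 2) # within 0.1% of range
  covs <- array(diag(2), c(2, 2, k))
  m <- manualModelMv(rep(1 / k, k), centers, covs)
  rng <- matrix(c(-5, 5, -5, 5), 2, 2, byrow = TRUE)
  cc <- findDensityPeaks(m, rng, valleyThreshold = 0, minPeakMass = 0)
  expect_identical(nFound(cc), 1L)
  expect_lt(max(abs(clusterCenters(cc))), 0.1)
})

test_that("three separated clusters yield three centers near the truth", {
  d <- threeClusterData(400, sep = 6, seed = 31)
  m <- overcluster(d$X, 12, fitOptions(seed = 31))
  cc <- findDensityPeaks(m, t(apply(d$X, 2, range)))
  expect_identical(nFound(cc), 3L)
  err <- apply(d$centers, 1, function(tc) {
    min(sqrt(rowSums(sweep(clusterCenters(cc), 2, tc)^2)))
  })
  expect_lt(max(err), 0.5)
})

test_that("peak count is invariant to the number of overclustering Gaussians", {
  d <- threeClusterData(500, sep = 6, seed = 8)
  rng <- t(apply(d$X, 2, range))
  found <- sapply(c(8, 12, 16), function(k) {
    nFound(findDensityPeaks(overcluster(d$X, k, fitOptions(seed = 4)), rng))
  })
  expect_identical(found, rep(3L, 3))
})

test_that("degenerate single-cluster data collapse to one found cluster", {
  set.seed(15)
  X <- matrix(rnorm(900 * 5), ncol = 5)
  m <- overcluster(X, 12, quickOpts(2, nReplicates = 5))
  cc <- findDensityPeaks(m, t(apply(X, 2, range)))
  expect_identical(nFound(cc), 1L)
  res <- classifySpikes(X, cc, quickOpts(2))
  expect_true(all(spikeLabels(res) == 1L))
  expect_equal(spikePosteriors(res), rep(1, 900))
})

test_that("MAP classification is near-perfect on separated clusters and ties break low", {
  d <- threeClusterData(300, sep = 7, seed = 77)
  res <- classifySpikes(d$X, d$centers, quickOpts(6))
  tab <- contingencyTable(d$labels, spikeLabels(res))
  expect_gte(miNorm(tab), 95)
  expect_gt(mean(spikePosteriors(res)), 0.95)
  # exact posterior tie: equidistant point between two identical components
  m <- manualModelMv(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
                     array(diag(2), c(2, 2, 2)))
  r <- posteriorResponsibilities(m, matrix(c(0, 0), 1, 2))
  expect_equal(r[1, ], c(0.5, 0.5))
  lab <- max.col(r, ties.method = "first")
  expect_identical(lab, 1L)
})

test_that("identical seeds give bit-identical sorting results", {
  wfs <- synthesize(simulationSpec(duration = 8, firingRates = 10, seed = 3),
                    "waveforms")
  a <- sortSpikes(wfs, method = "wd", metric = "i_peak",
                  options = quickOpts(nReplicates = 2), seed = 11)
  b <- sortSpikes(wfs, method = "wd", metric = "i_peak",
                  options = quickOpts(nReplicates = 2), seed = 11)
  expect_identical(spikeLabels(a), spikeLabels(b))
  expect_identical(spikePosteriors(a), spikePosteriors(b))
  expect_identical(clusterCenters(a), clusterCenters(b))
})

test_that("permuting cluster ids leaves MI_norm unchanged", {
  d <- threeClusterData(200, sep = 6, seed = 9)
  res <- classifySpikes(d$X, d$centers, quickOpts(1))
  lab <- spikeLabels(res)
  perm <- c(2L, 3L, 1L)[lab]
  expect_equal(miNorm(contingencyTable(d$labels, lab)),
               miNorm(contingencyTable(d$labels, perm)))
})

test_that("outlier handling flags injected outliers and preserves core labels", {
  d <- threeClusterData(250, sep = 7, seed = 13)
  set.seed(99)
  outliers <- matrix(runif(15 * 5, -15, 25), 15, 5)
  X <- rbind(d$X, outliers)
  om <- handleOutliers(X, kNN = 20)
  expect_identical(length(om$core), nrow(X))
  # most injected outliers flagged, almost no core points flagged
  expect_gt(mean(!om$core[751:765]), 0.6)
  expect_lt(mean(!om$core[1:750]), 0.05)
  # generous cutoff keeps everything
  om2 <- handleOutliers(d$X, kNN = 10, cutoff = 1e6)
  expect_true(all(om2$core))
  expect_error(handleOutliers(d$X, kNN = 10, cutoff = 1e-9), "misconfiguration")
  expect_error(handleOutliers(d$X, kNN = 0), "kNN")
})

test_that("classification with outlier handling matches the clean run when nothing is excluded", {
  d <- threeClusterData(150, sep = 7, seed = 21)
  wfs <- synthesize(simulationSpec(duration = 8, firingRates = 12, seed = 5),
                    "waveforms")
  plain <- sortSpikes(wfs, method = "pca", metric = "var",
                      options = quickOpts(nReplicates = 2), seed = 2)
  lenient <- sortSpikes(wfs, method = "pca", metric = "var",
                        options = quickOpts(nReplicates = 2), seed = 2,
                        outlierHandling = TRUE, outlierCutoff = 1e9)
  expect_identical(spikeLabels(plain), spikeLabels(lenient))
})

test_that("mergeClusters relabels without touching spike correspondence", {
  d <- threeClusterData(200, sep = 6, seed = 17)
  res <- classifySpikes(d$X, d$centers, quickOpts(3))
  merged <- mergeClusters(res, c(2L, 3L))
  expect_identical(nFound(merged), 2L)
  expect_identical(length(spikeLabels(merged)), length(spikeLabels(res)))
  was23 <- spikeLabels(res) %in% c(2L, 3L)
  expect_true(all(spikeLabels(merged)[was23] == 2L))
  expect_identical(spikeLabels(merged)[!was23], spikeLabels(res)[!was23])
  expect_error(mergeClusters(res, c(2L, 9L)), "out of range")
})
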