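# hand-built mixture model (bypasses fitting) for metric and density tests
manualModel <- function(weights, means, sds) {
  k <- length(weights)
  new("MixtureModel",
    weights = weights / sum(weights),
    means = matrix(means, ncol = 1L),
    covariances = array(sds^2, dim = c(1L, 1L, k)),
    logLik = NA_real_, logLikTrace = numeric(), converged = TRUE,
    nIterations = 1L, diagnostics = list()
  )
}

manualModelMv <- function(weights, means, covs) {
  k <- length(weights)
  new("MixtureModel",
    weights = weights / sum(weights),
    means = means,
    covariances = covs,
    logLik = NA_real_, logLikTrace = numeric(), converged = TRUE,
    nIterations = 1L, diagnostics = list()
  )
}

# three spherical unit-variance clusters in 5-D separated by `sep` sigma
threeClusterData <- function(nPerCluster, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, 5), rep(sep, 5), c(sep, 0, 0, sep, 0))
  X <- do.call(rbind, lapply(1:3, function(j) {
    sweep(matrix(rnorm(nPerCluster * 5), ncol = 5), 2, centers[j, ], "+")
  }))
  list(X = X, labels = rep(1:3, each = nPerCluster), centers = centers)
}

quickOpts <- function(seed = 1, nReplicates = 3) {
  fitOptions(nReplicates = nReplicates, seed = seed)
}
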