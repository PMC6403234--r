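#' EM fitting options
#'
#' Controls for the expectation-maximization runs used throughout the
#' pipeline. Defaults follow the sorting framework's stated protocol: 10
#' random restarts per fit, an iteration cap of 1e4 EM cycles, and
#' convergence when the log-likelihood changes by less than 1e-6 percent
#' between cycles.
#'
#' @param nReplicates number of random restarts; the replicate with highest
#'   final log-likelihood is returned.
#' @param maxIterations cap on full EM cycles per replicate.
#' @param relTol convergence threshold, as a *percentage* change of
#'   log p(x) between successive cycles. The default 1e-4 percent equals a
#'   relative change of 1e-6, the conventional mixture-EM stopping
#'   criterion.
#' @param covarianceFloor ridge added to covariance diagonals each M-step,
#'   expressed as a fraction of the per-dimension data variance. Prevents
#'   singular components.
#' @param seed integer root seed, or NULL for the session RNG. Replicate r
#'   runs from a deterministic child seed so fits are exactly repeatable.
#' @return a list of class `FitOptions`.
#' @export
fitOptions <- function(nReplicates = 10L, maxIterations = 10000L,
                       relTol = 1e-4, covarianceFloor = 1e-6, seed = NULL) {
  stopifnot(
    nReplicates >= 1L, maxIterations >= 1L, relTol > 0, covarianceFloor >= 0
  )
  out <- list(
    nReplicates = as.integer(nReplicates),
    maxIterations = as.integer(maxIterations),
    relTol = as.numeric(relTol),
    covarianceFloor = as.numeric(covarianceFloor),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(out) <- "FitOptions"
  out
}

# deterministic child seed for replicate/stage r of a root seed
childSeed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 16807) %% 2147483647L)
}

asDataMatrix <- function(data) {
  if (is(data, "FeatureMatrix")) data <- featureValues(data)
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("data contain non-finite values")
  data
}

# random initialization: k distinct observations as means, data covariance
# for every component, uniform weights
initGmm <- function(data, k, floorVec) {
  n <- nrow(data)
  idx <- sample.int(n, k)
  means <- data[idx, , drop = FALSE]
  S <- stats::cov(data)
  if (nrow(data) < 2L) S <- diag(ncol(data))
  S <- S + diag(floorVec, ncol(data))
  covs <- array(S, dim = c(ncol(data), ncol(data), k))
  list(weights = rep(1 / k, k), means = means, covs = covs)
}

# k-means initialization: component means at the cell centroids, covariances
# from the within-cell scatter, weights from the cell occupancies. Starts
# every component tight inside one region of the data, which keeps EM from
# settling on components that bridge disjoint clusters.
initGmmKmeans <- function(data, k, floorVec) {
  d <- ncol(data)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(data, k, nstart = 1L, iter.max = 30L)),
    error = function(e) NULL
  )
  if (is.null(km)) return(initGmm(data, k, floorVec))
  S0 <- stats::cov(data)
  covs <- array(0, dim = c(d, d, k))
  for (j in seq_len(k)) {
    cell <- data[km$cluster == j, , drop = FALSE]
    Sj <- if (nrow(cell) > d + 1L) stats::cov(cell) else S0
    covs[, , j] <- Sj + diag(floorVec, d)
  }
  w <- pmax(tabulate(km$cluster, k), 1) / nrow(data)
  list(weights = w / sum(w), means = km$centers, covs = covs)
}

newMixtureModel <- function(fit, diagnostics = list()) {
  w <- fit$weights / sum(fit$weights)
  new("MixtureModel",
    weights = as.numeric(w),
    means = fit$means,
    covariances = fit$covariances,
    logLik = as.numeric(fit$logLik),
    logLikTrace = as.numeric(fit$logLikTrace),
    converged = isTRUE(fit$converged),
    nIterations = as.integer(fit$nIterations),
    diagnostics = diagnostics
  )
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Runs `options$nReplicates` EM fits from random initializations (means
#' drawn as k distinct observations, covariances set to the data covariance,
#' uniform weights) and returns the replicate with the highest final
#' log-likelihood. The per-iteration log-likelihood of the winning replicate
#' is retained in the model's `logLikTrace`; EM guarantees it is
#' non-decreasing.
#'
#' @param data observations x d numeric matrix (a vector is treated as
#'   univariate), or a [FeatureMatrix-class].
#' @param k number of mixture components.
#' @param options a [fitOptions()] list.
#' @param init per-replicate initialization: `"random"` (default) draws k
#'   distinct observations as means with the data covariance for every
#'   component — a heavily overlapped start that suits density-estimation
#'   fits; `"kmeans"` seeds each component inside one k-means cell with the
#'   within-cell covariance, which suits partition-like fits
#'   (overclustering) because it avoids components that bridge disjoint
#'   clusters.
#' @return a [MixtureModel-class].
#' @examples
#' x <- c(rnorm(300, -4), rnorm(300, 4))
#' m <- fitGmm(x, k = 2, options = fitOptions(nReplicates = 3, seed = 1))
#' mixtureMeans(m)
#' @export
fitGmm <- function(data, k, options = fitOptions(),
                   init = c("random", "kmeans")) {
  init <- match.arg(init)
  data <- asDataMatrix(data)
  k <- as.integer(k)
  if (nrow(data) < k)
    stop("need at least as many observations (", nrow(data),
         ") as components (", k, ")")
  d <- ncol(data)
  vars <- apply(data, 2, stats::var)
  if (nrow(data) < 2L) vars <- rep(1, d)
  if (all(vars == 0))
    stop("all observations are identical; a mixture model is degenerate ",
         "(covarianceFloor > 0 required and k = 1 recommended)")
  floorVec <- options$covarianceFloor * pmax(vars, max(vars) * 1e-12)

  if (!is.null(options$seed)) {
    repSeeds <- vapply(seq_len(options$nReplicates),
                       function(r) childSeed(options$seed, r), integer(1))
  } else {
    repSeeds <- sample.int(.Machine$integer.max, options$nReplicates)
  }

  best <- NULL
  repLogLik <- numeric(options$nReplicates)
  for (r in seq_len(options$nReplicates)) {
    set.seed(repSeeds[r])
    start <- if (init == "kmeans") initGmmKmeans(data, k, floorVec) else
      initGmm(data, k, floorVec)
    fit <- em_gmm_cpp(data, start$weights, start$means, start$covs,
                      options$maxIterations, options$relTol, floorVec,
                      fixed_means = FALSE)
    repLogLik[r] <- fit$logLik
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  newMixtureModel(best, diagnostics = list(
    replicateLogLik = repLogLik, replicateSeeds = repSeeds,
    fixedMeans = FALSE, options = options, init = init
  ))
}

#' Fit a fixed-mean Gaussian mixture
#'
#' EM variant in which component centers are held at `fixedMeans` for the
#' whole run: only the weights and covariances are updated in the M-step, so
#' the returned means are bit-identical to the input. Used for the final
#' classification step, where the centers are the density peaks found by
#' [findDensityPeaks()]. A component that captures essentially no posterior
#' mass is kept alive with its weight clamped to 1e-12 and its covariance at
#' the regularization floor (with a warning), because downstream cluster
#' identity depends on the component count.
#'
#' @inheritParams fitGmm
#' @param fixedMeans k x d matrix (or length-k vector for univariate data)
#'   of component centers to hold fixed.
#' @return a [MixtureModel-class] whose `means` equal `fixedMeans` exactly.
#' @export
fitGmmFixedMeans <- function(data, fixedMeans, options = fitOptions()) {
  data <- asDataMatrix(data)
  if (is.vector(fixedMeans)) fixedMeans <- matrix(fixedMeans, ncol = 1L)
  fixedMeans <- as.matrix(fixedMeans)
  storage.mode(fixedMeans) <- "double"
  if (!nrow(fixedMeans)) stop("fixedMeans must be non-empty")
  if (any(!is.finite(fixedMeans))) stop("fixedMeans must be finite")
  if (ncol(fixedMeans) != ncol(data))
    stop("fixedMeans dimension does not match the data")
  k <- nrow(fixedMeans)
  if (nrow(data) < k)
    stop("need at least as many observations as components")
  vars <- apply(data, 2, stats::var)
  if (nrow(data) < 2L || all(vars == 0)) vars <- pmax(vars, 1)
  floorVec <- options$covarianceFloor * pmax(vars, max(vars) * 1e-12)

  S <- stats::cov(data) + diag(floorVec, ncol(data))
  covs <- array(S, dim = c(ncol(data), ncol(data), k))
  fit <- em_gmm_cpp(data, rep(1 / k, k), fixedMeans, covs,
                    options$maxIterations, options$relTol, floorVec,
                    fixed_means = TRUE)
  if (isTRUE(fit$emptyComponent))
    warning("one or more fixed-mean components captured no posterior mass; ",
            "weight clamped to 1e-12 and covariance floored")
  fit$means <- fixedMeans  # bit-exact contract
  newMixtureModel(fit, diagnostics = list(
    fixedMeans = TRUE, options = options
  ))
}

checkDims <- function(model, points) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != ncol(model@means))
    stop("point dimensionality (", ncol(points),
         ") does not match the model (", ncol(model@means), ")")
  points
}

#' Mixture density
#'
#' Evaluates \eqn{p(x) = \sum_i \alpha_i N(x \mid \mu_i, \Sigma_i)} at the
#' given points.
#'
#' @param model a [MixtureModel-class].
#' @param points points x d matrix (vector for univariate models).
#' @param log return log densities.
#' @return numeric vector of (log-)densities.
#' @export
modelDensity <- function(model, points, log = FALSE) {
  points <- checkDims(model, points)
  ld <- gmm_logdensity_cpp(points, model@weights, model@means,
                           model@covariances)
  if (log) as.numeric(ld) else exp(as.numeric(ld))
}

#' Posterior component responsibilities
#'
#' The E-step quantities: for each point, the posterior probability of each
#' mixture component. Rows are non-negative and sum to 1.
#'
#' @inheritParams modelDensity
#' @return points x k matrix of responsibilities.
#' @export
posteriorResponsibilities <- function(model, points) {
  points <- checkDims(model, points)
  gmm_responsibilities_cpp(points, model@weights, model@means,
                           model@covariances)
}
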