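#' Score features for clustering separability
#'
#' Computes one separability score per feature column. For the GMM-based
#' metrics an eight-component univariate Gaussian mixture is fitted to the
#' feature's empirical distribution and the score is derived from the fitted
#' density:
#' \describe{
#'   \item{`i_peak`}{sum of the density at its local maxima, normalized by
#'     the highest density on a 100-point grid over the data range — roughly
#'     the number of modes.}
#'   \item{`i_inf`}{same normalized sum over the inflection points of the
#'     density.}
#'   \item{`i_dist`}{median over all component pairs of
#'     \eqn{D_{ij} = |\mu_i - \mu_j| \sqrt{\alpha_i \alpha_j} /
#'     (\sigma_i \sigma_j)} — the weight-scaled, SD-normalized distance
#'     between Gaussians.}
#'   \item{`var`}{the raw variance of the feature (no GMM).}
#' }
#' Multimodal features score high, unimodal features low; the scores drive
#' feature selection ([selectTop()]) and wPCA weighting ([weightedPca()]).
#'
#' Columns flagged zero-variance, and columns whose mixture fit fails,
#' receive score 0 (with a warning) and are never selected. For speed, GMM
#' fits use at most `maxPoints` observations per feature (uniform random
#' subsample, seeded from `options$seed`).
#'
#' @param features a [FeatureMatrix-class] or plain matrix.
#' @param metric one of "var", "i_peak", "i_inf", "i_dist".
#' @param options a [fitOptions()] list controlling the univariate fits.
#' @param k number of Gaussians in each univariate fit (default 8).
#' @param maxPoints subsampling cap per feature for the univariate fits.
#' @return a [SeparabilityScore-class].
#' @export
scoreFeatures <- function(features, metric = c("i_dist", "i_peak", "i_inf",
                                               "var"),
                          options = fitOptions(), k = 8L,
                          maxPoints = 50000L) {
  metric <- match.arg(metric)
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else
    as.matrix(features)
  info <- if (is(features, "FeatureMatrix")) featureInfo(features) else
    data.frame(id = paste0("f", seq_len(ncol(X))), method = "unknown",
               stringsAsFactors = FALSE)
  m <- ncol(X)

  if (metric == "var") {
    sc <- apply(X, 2L, stats::var)
    return(new("SeparabilityScore",
      metric = metric, scores = as.numeric(sc),
      models = list(), grids = list(), featureInfo = info
    ))
  }

  if (nrow(X) < k)
    stop("GMM-based metrics need at least ", k, " observations")
  scores <- numeric(m)
  models <- vector("list", m)
  grids <- vector("list", m)
  failed <- 0L
  for (j in seq_len(m)) {
    x <- X[, j]
    if (stats::var(x) == 0) {
      failed <- failed + 1L
      next
    }
    if (length(x) > maxPoints) {
      if (!is.null(options$seed)) set.seed(childSeed(options$seed, 70000L + j))
      x <- x[sample.int(length(x), maxPoints)]
    }
    colOpts <- options
    if (!is.null(options$seed)) colOpts$seed <- childSeed(options$seed, j)
    fit <- tryCatch(fitGmm(x, k = k, options = colOpts), error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    models[[j]] <- fit
    if (metric == "i_dist") {
      scores[j] <- iDist(fit)
    } else {
      pi <- peaksAndInflections(fit, range(X[, j]))
      grids[[j]] <- pi$grid
      scores[j] <- if (metric == "i_peak") {
        iPeak(fit, pi)
      } else {
        iInf(fit, pi)
      }
    }
  }
  if (failed > 0L)
    warning(failed, " degenerate feature(s) scored 0 and will never be selected")
  new("SeparabilityScore",
    metric = metric, scores = scores, models = models, grids = grids,
    featureInfo = info
  )
}

#' Locate peaks and inflection points of a univariate mixture density
#'
#' The fitted density is discretized on 100 equally spaced points spanning
#' the data range; peaks are sign changes (+ to -) of the first finite
#' difference, inflection points are sign changes (either direction) of the
#' second finite difference. A plateau (a run of zero differences) counts as
#' a single event located at its left edge.
#'
#' @param model a univariate [MixtureModel-class].
#' @param dataRange length-2 numeric: the (min, max) of the data the model
#'   was fitted to.
#' @param nGrid grid resolution (default 100).
#' @return list with `grid` (the evaluation points), `density`, `peaks` and
#'   `inflections` (values of the grid points where each event occurs).
#' @export
peaksAndInflections <- function(model, dataRange, nGrid = 100L) {
  if (ncol(model@means) != 1L) stop("model must be univariate")
  dataRange <- range(dataRange)
  grid <- seq(dataRange[1], dataRange[2], length.out = nGrid)
  p <- modelDensity(model, grid)
  list(
    grid = grid, density = p,
    peaks = grid[signChangeIdx(diff(p), "down")],
    inflections = grid[signChangeIdx(diff(p, differences = 2L), "any")]
  )
}

# indices (into the vector being differenced, offset so they address the
# grid point at the event) where the sign of d changes; plateaus collapse to
# their left edge
signChangeIdx <- function(d, direction = c("down", "any")) {
  direction <- match.arg(direction)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer())
  runs <- s[nz]
  chg <- which(runs[-length(runs)] != runs[-1])
  if (direction == "down")
    chg <- chg[runs[chg] > 0]
  # event sits between nz[chg] and nz[chg + 1]; take the left edge + 1,
  # which is the grid point where the slope has just turned
  nz[chg] + 1L
}

#' @rdname separabilityMetrics
#' @export
iPeak <- function(model, pi = NULL, dataRange = NULL) {
  if (is.null(pi)) pi <- peaksAndInflections(model, dataRange)
  mx <- max(pi$density)
  stopifnot(mx > 0)
  sum(modelDensity(model, pi$peaks)) / mx
}

#' @rdname separabilityMetrics
#' @export
iInf <- function(model, pi = NULL, dataRange = NULL) {
  if (is.null(pi)) pi <- peaksAndInflections(model, dataRange)
  mx <- max(pi$density)
  stopifnot(mx > 0)
  sum(modelDensity(model, pi$inflections)) / mx
}

#' GMM-based separability metrics
#'
#' `iPeak` and `iInf` sum the mixture density at its peaks (resp. inflection
#' points), normalized by the maximum density on the 100-point grid, so a
#' unimodal density scores close to 1 (resp. about `2 exp(-1/2)`). `iDist`
#' is the median over all unordered component pairs of the normalized
#' between-Gaussian distance
#' \eqn{D_{ij} = |\mu_i - \mu_j| \sqrt{\alpha_i \alpha_j} /
#' (\sigma_i \sigma_j)}: pairs of well-populated, well-separated, tight
#' Gaussians score high.
#'
#' @param model a univariate [MixtureModel-class] (k >= 2 for `iDist`).
#' @param pi optional precomputed [peaksAndInflections()] result.
#' @param dataRange data range used when `pi` is not supplied.
#' @return a non-negative scalar score.
#' @name separabilityMetrics
#' @export
iDist <- function(model) {
  if (ncol(model@means) != 1L) stop("iDist is defined for univariate models")
  k <- length(model@weights)
  if (k < 2L) stop("iDist needs at least 2 components")
  mu <- as.numeric(model@means)
  sigma <- sqrt(as.numeric(model@covariances[1L, 1L, ]))
  alpha <- model@weights
  ok <- sigma > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance component(s) excluded from iDist")
    mu <- mu[ok]; sigma <- sigma[ok]; alpha <- alpha[ok]
    if (length(mu) < 2L) return(0)
  }
  pairs <- utils::combn(length(mu), 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  D <- abs(mu[i] - mu[j]) * sqrt(alpha[i] * alpha[j]) / (sigma[i] * sigma[j])
  stats::median(D)
}

#' Select the top-scoring features
#'
#' Returns the column indices of the `nKeep` highest separability scores.
#' Ties are broken toward the lower column index, so selection is
#' deterministic. Zero-score (degenerate) features are never selected unless
#' fewer than `nKeep` informative features exist, in which case all
#' informative ones are kept with a warning.
#'
#' @param scores a [SeparabilityScore-class] or a plain numeric vector.
#' @param nKeep number of features to keep (default 5).
#' @return integer column indices, ordered by decreasing score.
#' @export
selectTop <- function(scores, nKeep = 5L) {
  sc <- if (is(scores, "SeparabilityScore")) scores@scores else
    as.numeric(scores)
  nKeep <- as.integer(nKeep)
  if (nKeep > length(sc))
    stop("nKeep (", nKeep, ") exceeds the number of features (",
         length(sc), ")")
  informative <- sum(sc > 0)
  if (informative < nKeep) {
    warning("only ", informative, " informative feature(s); keeping all")
    nKeep <- max(informative, 1L)
  }
  order(-sc, seq_along(sc))[seq_len(nKeep)]
}

#' Export a separability score table
#'
#' Writes feature_id, metric, score and rank as CSV.
#'
#' @param scores a [SeparabilityScore-class].
#' @param path output file.
#' @return the table, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  tab <- data.frame(
    feature_id = scores@featureInfo$id,
    metric = scores@metric,
    score = scores@scores,
    rank = rank(-scores@scores, ties.method = "first")
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
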