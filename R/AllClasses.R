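#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gmmsort, .registration = TRUE
NULL

#' WaveformSet: detected spike waveforms
#'
#' Container for a set of spike waveforms cut from one or more channels of an
#' extracellular recording. Waveforms are stored as a spikes-by-samples
#' matrix; for multi-channel groups (e.g. tetrodes) the per-channel snippets
#' are concatenated along the sample axis in a fixed channel order, so that
#' `ncol(waveforms) == nChannels * samplesPerChannel`.
#'
#' @slot waveforms numeric matrix, spikes x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot nChannels number of concatenated channels.
#' @slot samplesPerChannel snippet length per channel.
#' @slot spikeTimes sample index of each spike peak in the source trace
#'   (empty when waveforms were supplied pre-cut).
#' @slot trueLabels optional integer ground-truth class per spike (0 =
#'   background/unmatched); empty when unknown.
#' @slot metadata free-form list (channel order, detection settings, ...).
#'
#' @exportClass WaveformSet
setClass("WaveformSet",
  representation(
    waveforms = "matrix",
    samplingRate = "numeric",
    nChannels = "integer",
    samplesPerChannel = "integer",
    spikeTimes = "numeric",
    trueLabels = "integer",
    metadata = "list"
  )
)

setValidity("WaveformSet", function(object) {
  msg <- character()
  if (!is.numeric(object@waveforms))
    msg <- c(msg, "waveforms must be a numeric matrix")
  if (any(!is.finite(object@waveforms)))
    msg <- c(msg, "waveforms contain non-finite values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (ncol(object@waveforms) != object@nChannels * object@samplesPerChannel)
    msg <- c(msg, "ncol(waveforms) must equal nChannels * samplesPerChannel")
  if (length(object@trueLabels) &&
      length(object@trueLabels) != nrow(object@waveforms))
    msg <- c(msg, "trueLabels length must match the number of spikes")
  if (length(object@spikeTimes) &&
      length(object@spikeTimes) != nrow(object@waveforms))
    msg <- c(msg, "spikeTimes length must match the number of spikes")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveformSet
#'
#' @param waveforms spikes x samples numeric matrix (channels concatenated).
#' @param samplingRate sampling rate in Hz.
#' @param nChannels number of concatenated channels (default 1).
#' @param spikeTimes optional per-spike peak sample index in the source trace.
#' @param trueLabels optional per-spike integer ground-truth class.
#' @param metadata optional list of provenance information.
#' @return a [WaveformSet-class] object.
#' @export
WaveformSet <- function(waveforms, samplingRate, nChannels = 1L,
                        spikeTimes = numeric(), trueLabels = integer(),
                        metadata = list()) {
  waveforms <- as.matrix(waveforms)
  storage.mode(waveforms) <- "double"
  nChannels <- as.integer(nChannels)
  spc <- ncol(waveforms) %/% nChannels
  new("WaveformSet",
    waveforms = waveforms, samplingRate = as.numeric(samplingRate),
    nChannels = nChannels, samplesPerChannel = as.integer(spc),
    spikeTimes = as.numeric(spikeTimes),
    trueLabels = as.integer(trueLabels), metadata = metadata
  )
}

#' MixtureModel: a fitted Gaussian mixture
#'
#' Parameters of a k-component Gaussian mixture
#' \eqn{p(x) = \sum_i \alpha_i N(x \mid \mu_i, \Sigma_i)} in d dimensions
#' (d = 1 for the univariate fits used in feature scoring), together with fit
#' diagnostics from the expectation-maximization run that produced it.
#'
#' @slot weights mixing proportions (alpha), non-negative, summing to 1.
#' @slot means k x d matrix of component centers.
#' @slot covariances d x d x k array of component covariances.
#' @slot logLik total data log-likelihood at the final iteration.
#' @slot logLikTrace per-iteration log-likelihood of the winning replicate.
#' @slot converged TRUE if the relative log-likelihood change fell under the
#'   convergence threshold before the iteration cap.
#' @slot nIterations EM cycles run in the winning replicate.
#' @slot diagnostics list: per-replicate log-likelihoods and seeds, fixed-mean
#'   flag, options used.
#'
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(
    weights = "numeric",
    means = "matrix",
    covariances = "array",
    logLik = "numeric",
    logLikTrace = "numeric",
    converged = "logical",
    nIterations = "integer",
    diagnostics = "list"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  k <- length(object@weights)
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 within 1e-12")
  if (nrow(object@means) != k)
    msg <- c(msg, "means must have one row per component")
  if (length(dim(object@covariances)) != 3L ||
      dim(object@covariances)[3] != k)
    msg <- c(msg, "covariances must be a d x d x k array")
  d <- ncol(object@means)
  if (length(dim(object@covariances)) == 3L &&
      !all(dim(object@covariances)[1:2] == d))
    msg <- c(msg, "covariance dimensions must match the mean dimension")
  for (j in seq_len(k)) {
    S <- object@covariances[, , j, drop = FALSE]
    dim(S) <- c(d, d)
    if (any(abs(S - t(S)) > 1e-8 * (1 + max(abs(S)))))
      msg <- c(msg, sprintf("covariance %d is not symmetric", j))
    else if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      msg <- c(msg, sprintf("covariance %d is not positive definite", j))
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: candidate features per spike
#'
#' Spikes-by-features value matrix with per-column provenance: which
#' transform produced the column (PCA component, Haar wavelet coefficient at
#' a given scale and translation, or weighted-PC) and the configuration used.
#'
#' @slot values spikes x features numeric matrix.
#' @slot featureInfo data.frame, one row per column of `values`: columns
#'   `id`, `method` ("pca", "wd" or "wpca"), `scale`, `translation`,
#'   `component`, `channel`, `padded`.
#' @slot methodParams list recording the transform configuration (e.g. PCA
#'   loadings, wavelet levels, wPCA weights).
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    featureInfo = "data.frame",
    methodParams = "list"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != nrow(object@featureInfo))
    msg <- c(msg, "featureInfo must have one row per feature column")
  if (!all(c("id", "method") %in% names(object@featureInfo)))
    msg <- c(msg, "featureInfo must contain 'id' and 'method' columns")
  if (length(msg)) msg else TRUE
})

#' SeparabilityScore: per-feature clustering separability
#'
#' One score per candidate feature, computed either from the raw variance or
#' from an eight-component univariate Gaussian mixture fitted to the
#' feature's empirical distribution (peak-, inflection- or distance-based
#' metrics).
#'
#' @slot metric one of "var", "i_peak", "i_inf", "i_dist".
#' @slot scores non-negative numeric, one per feature.
#' @slot models list of univariate [MixtureModel-class] fits (empty for
#'   metric "var"; NULL entries for degenerate features).
#' @slot grids list of the 100-point density grids used per feature.
#' @slot featureInfo the scored features' provenance table.
#'
#' @exportClass SeparabilityScore
setClass("SeparabilityScore",
  representation(
    metric = "character",
    scores = "numeric",
    models = "list",
    grids = "list",
    featureInfo = "data.frame"
  )
)

setValidity("SeparabilityScore", function(object) {
  msg <- character()
  if (!object@metric %in% c("var", "i_peak", "i_inf", "i_dist"))
    msg <- c(msg, "metric must be one of var, i_peak, i_inf, i_dist")
  if (any(!is.finite(object@scores)) || any(object@scores < 0))
    msg <- c(msg, "scores must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' ClusterCenters: density peaks of the overclustered mixture
#'
#' Cluster centers estimated as local maxima of an overclustered mixture
#' density, after merging peaks closer than 1% of the data range.
#'
#' @slot centers n_found x d matrix of retained peak locations.
#' @slot searchTrace data.frame with one row per Nelder-Mead start:
#'   start coordinates, endpoint, log-density, convergence flag, and the
#'   index of the merged peak it was assigned to (NA if discarded).
#' @slot dataRange d x 2 matrix of per-dimension (min, max) used for merging.
#' @slot mergeThreshold range-normalized distance under which peaks merge.
#'
#' @exportClass ClusterCenters
setClass("ClusterCenters",
  representation(
    centers = "matrix",
    searchTrace = "data.frame",
    dataRange = "matrix",
    mergeThreshold = "numeric"
  )
)

setValidity("ClusterCenters", function(object) {
  msg <- character()
  if (nrow(object@centers) < 1L)
    msg <- c(msg, "at least one center is required")
  rng <- object@dataRange
  if (ncol(object@centers) != nrow(rng))
    msg <- c(msg, "centers and dataRange dimensions disagree")
  else {
    ext <- rng[, 2] - rng[, 1]
    tol <- object@mergeThreshold
    low <- sweep(object@centers, 2, rng[, 1] - tol * ext, ">=")
    high <- sweep(object@centers, 2, rng[, 2] + tol * ext, "<=")
    if (!all(low & high))
      msg <- c(msg, "centers must lie within the data bounding box (+/- merge threshold)")
    if (nrow(object@centers) > 1L) {
      sc <- sweep(object@centers, 2, ext, "/")
      dmin <- min(dist(sc))
      if (dmin <= object@mergeThreshold)
        msg <- c(msg, "retained centers must be farther apart than the merge threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SortingResult: final spike classification
#'
#' Output of the full sorting pipeline: the selected features, the final
#' fixed-mean mixture, and a maximum a posteriori cluster label with its
#' posterior probability for every spike.
#'
#' @slot labels integer cluster id per spike, in 1..nFound.
#' @slot posteriors per-spike maximum a posteriori probability, in (0, 1].
#' @slot model the final fixed-mean [MixtureModel-class].
#' @slot centers the [ClusterCenters-class] used as fixed means.
#' @slot featureInfo provenance of the selected features.
#' @slot outlierMask optional logical, TRUE for spikes excluded from model
#'   fitting and reinserted by template matching.
#' @slot config list of the effective pipeline configuration.
#'
#' @exportClass SortingResult
setClass("SortingResult",
  representation(
    labels = "integer",
    posteriors = "numeric",
    model = "MixtureModel",
    centers = "ClusterCenters",
    featureInfo = "data.frame",
    outlierMask = "logical",
    config = "list"
  )
)

setValidity("SortingResult", function(object) {
  msg <- character()
  k <- nrow(object@centers@centers)
  if (length(object@labels) != length(object@posteriors))
    msg <- c(msg, "labels and posteriors must have the same length")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > k))
    msg <- c(msg, "labels must be in 1..n_found")
  if (length(object@posteriors) &&
      (any(object@posteriors <= 0) || any(object@posteriors > 1)))
    msg <- c(msg, "posteriors must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' RawRecording: continuous extracellular traces
#'
#' Channels-by-samples continuous signal with optional ground-truth spike
#' times (from simulation or paired intracellular recording).
#'
#' @slot traces channels x samples numeric matrix.
#' @slot samplingRate Hz.
#' @slot truthTimes sample indices of true spike peaks (empty if unknown).
#' @slot truthLabels integer neuron id per truth time.
#' @slot metadata free-form list (units, simulation spec, ...).
#'
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    traces = "matrix",
    samplingRate = "numeric",
    truthTimes = "numeric",
    truthLabels = "integer",
    metadata = "list"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@truthTimes) != length(object@truthLabels))
    msg <- c(msg, "truthTimes and truthLabels must have the same length")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param traces channels x samples matrix (a vector is treated as one channel).
#' @param samplingRate Hz.
#' @param truthTimes,truthLabels optional ground-truth spike peak sample
#'   indices and neuron ids.
#' @param metadata optional list.
#' @return a [RawRecording-class] object.
#' @export
RawRecording <- function(traces, samplingRate, truthTimes = numeric(),
                         truthLabels = integer(), metadata = list()) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  new("RawRecording",
    traces = traces, samplingRate = as.numeric(samplingRate),
    truthTimes = as.numeric(truthTimes),
    truthLabels = as.integer(truthLabels), metadata = metadata
  )
}
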