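#' Sort a waveform set end-to-end
#'
#' Runs the full GMM-based sorting pipeline on cut waveforms:
#' \enumerate{
#'   \item feature construction — PCA scores (`method = "pca"`), Haar
#'     wavelet coefficients (`"wd"`), or separability-weighted PCA on the
#'     wavelet coefficients (`"wpca"`, the recommended strategy together
#'     with `metric = "i_dist"`);
#'   \item feature selection — for `pca`/`wd`, the `nFeatures`
#'     highest-ranked columns by the chosen separability metric; for
#'     `wpca`, the first `nFeatures` weighted PCs (variance order);
#'   \item overclustering with `nGaussians` full-covariance components,
#'     Nelder-Mead density-peak search and 1%-range peak merging;
#'   \item fixed-mean GMM classification: every spike is assigned to the
#'     cluster of highest posterior probability.
#' }
#' With `outlierHandling = TRUE`, spikes with extreme k-nearest-neighbor
#' distances are excluded from all mixture fits and reinserted at the
#' classification step by template matching under the final model.
#'
#' @param wfs a [WaveformSet-class].
#' @param method feature construction: "wpca" (default), "pca" or "wd".
#' @param metric separability metric: "i_dist" (default), "i_peak",
#'   "i_inf", or "var". `var` is rejected for `wpca`, where it would oppose
#'   the z-score normalization.
#' @param nFeatures number of features used for clustering (default 5).
#' @param nGaussians overclustering components (default 12, the single-wire
#'   setting; 20 is the tetrode setting).
#' @param univariateK Gaussians per univariate scoring fit (default 8).
#' @param options a [fitOptions()] list; its seed is overridden by `seed`
#'   when given.
#' @param outlierHandling exclude k-NN-distance outliers from fitting.
#' @param kNN,outlierCutoff forwarded to [handleOutliers()].
#' @param seed root seed for the whole run; identical seeds give identical
#'   results.
#' @return a [SortingResult-class].
#' @examples
#' wfs <- synthesize(simulationSpec(duration = 10, seed = 7), "waveforms")
#' res <- sortSpikes(wfs, method = "pca", metric = "var",
#'                   options = fitOptions(nReplicates = 2), seed = 1)
#' table(trueLabels(wfs), spikeLabels(res))
#' @export
sortSpikes <- function(wfs, method = c("wpca", "pca", "wd"),
                       metric = c("i_dist", "i_peak", "i_inf", "var"),
                       nFeatures = 5L, nGaussians = 12L, univariateK = 8L,
                       options = fitOptions(), outlierHandling = FALSE,
                       kNN = 20L, outlierCutoff = NULL, seed = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (method == "wpca" && metric == "var")
    stop("wpca requires a GMM-based metric (i_dist, i_peak or i_inf); ",
         "variance weighting would oppose the z-score normalization")
  if (!is.null(seed)) options$seed <- as.integer(seed)
  config <- list(
    method = method, metric = metric, nFeatures = nFeatures,
    nGaussians = nGaussians, univariateK = univariateK,
    options = unclass(options), outlierHandling = outlierHandling,
    kNN = kNN, outlierCutoff = outlierCutoff
  )

  scoreOpts <- options
  if (!is.null(options$seed)) scoreOpts$seed <- childSeed(options$seed, 101L)

  fitMask <- NULL
  if (outlierHandling) {
    # core-sample mask from the raw coefficient space (pre-selection)
    baseFeat <- if (method == "pca") pcaTransform(wfs) else haarWd(wfs)
    om <- handleOutliers(baseFeat, kNN = kNN, cutoff = outlierCutoff)
    fitMask <- om$core
    config$outlierCutoffUsed <- om$cutoff
    config$nOutliers <- sum(!om$core)
  }
  maskRows <- function(m) if (is.null(fitMask)) m else m[fitMask, , drop = FALSE]

  if (method == "pca") {
    feats <- pcaTransform(wfs)
    sc <- scoreFeatures(maskRows(featureValues(feats)), metric = metric,
                        options = scoreOpts, k = univariateK)
    sc@featureInfo <- featureInfo(feats)
    sel <- selectTop(sc, nFeatures)
  } else if (method == "wd") {
    feats <- haarWd(wfs)
    sc <- scoreFeatures(maskRows(featureValues(feats)), metric = metric,
                        options = scoreOpts, k = univariateK)
    sc@featureInfo <- featureInfo(feats)
    sel <- selectTop(sc, nFeatures)
  } else {
    coeffs <- haarWd(wfs)
    sc <- scoreFeatures(maskRows(featureValues(coeffs)), metric = metric,
                        options = scoreOpts, k = univariateK)
    sc@featureInfo <- featureInfo(coeffs)
    feats <- weightedPca(coeffs, separabilityScores(sc))
    sel <- seq_len(min(nFeatures, ncol(featureValues(feats))))
  }
  X <- featureValues(feats)[, sel, drop = FALSE]
  selInfo <- featureInfo(feats)[sel, , drop = FALSE]

  ocOpts <- options
  if (!is.null(options$seed)) ocOpts$seed <- childSeed(options$seed, 202L)
  model <- overcluster(maskRows(X), nGaussians = nGaussians, options = ocOpts)
  rng <- t(apply(maskRows(X), 2L, range))
  centers <- findDensityPeaks(model, rng)

  fmOpts <- options
  if (!is.null(options$seed)) fmOpts$seed <- childSeed(options$seed, 303L)
  res <- classifySpikes(X, centers, options = fmOpts,
                        featureInfo = selInfo, config = config,
                        fitMask = fitMask)
  res@config$scores <- separabilityScores(sc)
  res
}

#' Sort a raw recording
#'
#' Convenience wrapper: band-pass filters the traces, detects spikes,
#' optionally attaches ground-truth labels, and runs [sortSpikes()].
#'
#' @param rec a [RawRecording-class].
#' @param thresholdSd detection threshold in (robust) SD units.
#' @param low,high band edges in Hz.
#' @param window snippet samples per channel.
#' @param ... forwarded to [sortSpikes()].
#' @return list with `waveforms` (the labeled [WaveformSet-class]) and
#'   `result` (the [SortingResult-class]).
#' @export
sortRecording <- function(rec, thresholdSd = 5, low = 300, high = 3000,
                          window = 64L, ...) {
  filt <- bandpass(rec, low = low, high = high)
  wfs <- detectSpikes(filt, thresholdSd = thresholdSd, window = window)
  if (nSpikes(wfs) == 0L) stop("no spikes detected")
  if (length(truthTimes(rec))) {
    wfs <- matchGroundTruth(wfs, truthTimes(rec), truthLabels(rec))
  }
  list(waveforms = wfs, result = sortSpikes(wfs, ...))
}
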