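#' Accessors
#'
#' Accessor generics for the package's S4 containers. Slot access by `@` is
#' considered internal; use these.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("waveforms", function(object) standardGeneric("waveforms"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))
#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))
#' @rdname accessors
#' @export
setGeneric("mixtureCovariances",
           function(object) standardGeneric("mixtureCovariances"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("separabilityScores",
           function(object) standardGeneric("separabilityScores"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("nFound", function(object) standardGeneric("nFound"))
#' @rdname accessors
#' @export
setGeneric("spikeLabels", function(object) standardGeneric("spikeLabels"))
#' @rdname accessors
#' @export
setGeneric("spikePosteriors",
           function(object) standardGeneric("spikePosteriors"))
#' @rdname accessors
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("truthTimes", function(object) standardGeneric("truthTimes"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname accessors
#' @param object a WaveformSet
#' @export
setMethod("waveforms", "WaveformSet", function(object) object@waveforms)
#' @rdname accessors
#' @export
setMethod("samplingRate", "WaveformSet", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "RawRecording", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("nChannels", "WaveformSet", function(object) object@nChannels)
#' @rdname accessors
#' @export
setMethod("nChannels", "RawRecording", function(object) nrow(object@traces))
#' @rdname accessors
#' @export
setMethod("nSpikes", "WaveformSet", function(object) nrow(object@waveforms))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "WaveformSet", function(object) object@spikeTimes)
#' @rdname accessors
#' @export
setMethod("trueLabels", "WaveformSet", function(object) object@trueLabels)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("featureInfo", "FeatureMatrix", function(object) object@featureInfo)
#' @rdname accessors
#' @export
setMethod("featureInfo", "SeparabilityScore",
          function(object) object@featureInfo)
#' @rdname accessors
#' @export
setMethod("featureInfo", "SortingResult", function(object) object@featureInfo)
#' @rdname accessors
#' @export
setMethod("mixtureWeights", "MixtureModel", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("mixtureMeans", "MixtureModel", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("mixtureCovariances", "MixtureModel",
          function(object) object@covariances)
#' @rdname accessors
#' @export
setMethod("nComponents", "MixtureModel",
          function(object) length(object@weights))
#' @rdname accessors
#' @export
setMethod("isConverged", "MixtureModel", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("separabilityScores", "SeparabilityScore",
          function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusterCenters", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("clusterCenters", "SortingResult",
          function(object) object@centers@centers)
#' @rdname accessors
#' @export
setMethod("nFound", "ClusterCenters", function(object) nrow(object@centers))
#' @rdname accessors
#' @export
setMethod("nFound", "SortingResult",
          function(object) nrow(object@centers@centers))
#' @rdname accessors
#' @export
setMethod("spikeLabels", "SortingResult", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("spikePosteriors", "SortingResult",
          function(object) object@posteriors)
#' @rdname accessors
#' @export
setMethod("traces", "RawRecording", function(object) object@traces)
#' @rdname accessors
#' @export
setMethod("truthTimes", "RawRecording", function(object) object@truthTimes)
#' @rdname accessors
#' @export
setMethod("truthLabels", "RawRecording", function(object) object@truthLabels)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "MixtureModel", function(object, ...) {
  ll <- object@logLik
  attr(ll, "df") <- {
    k <- length(object@weights); d <- ncol(object@means)
    fm <- isTRUE(object@diagnostics$fixedMeans)
    (k - 1) + (if (fm) 0 else k * d) + k * d * (d + 1) / 2
  }
  class(ll) <- "logLik"
  ll
})

setMethod("show", "WaveformSet", function(object) {
  cat(sprintf(
    "WaveformSet: %d spikes, %d channel(s) x %d samples @ %g Hz\n",
    nrow(object@waveforms), object@nChannels, object@samplesPerChannel,
    object@samplingRate
  ))
  if (length(object@trueLabels)) {
    tb <- table(object@trueLabels)
    cat("  ground truth:", paste(sprintf("%s:%d", names(tb), tb),
                                 collapse = " "), "\n")
  }
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf(
    "MixtureModel: %d component(s), %d-dimensional\n  logLik %.4f after %d iteration(s)%s\n",
    length(object@weights), ncol(object@means), object@logLik,
    object@nIterations,
    if (object@converged) " (converged)" else " (iteration cap reached)"
  ))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix: %d spikes x %d features (%s)\n",
    nrow(object@values), ncol(object@values),
    paste(unique(object@featureInfo$method), collapse = "+")
  ))
})

setMethod("show", "SeparabilityScore", function(object) {
  cat(sprintf("SeparabilityScore (%s): %d features\n",
              object@metric, length(object@scores)))
  ord <- order(object@scores, decreasing = TRUE)
  top <- utils::head(ord, 5L)
  cat("  top:", paste(sprintf("%s=%.3g", object@featureInfo$id[top],
                              object@scores[top]), collapse = " "), "\n")
})

setMethod("show", "ClusterCenters", function(object) {
  cat(sprintf("ClusterCenters: %d peak(s) in %d dimension(s)\n",
              nrow(object@centers), ncol(object@centers)))
})

setMethod("show", "SortingResult", function(object) {
  cat(sprintf("SortingResult: %d spikes in %d cluster(s)\n",
              length(object@labels), nrow(object@centers@centers)))
  tb <- table(object@labels)
  cat("  sizes:", paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
  cat(sprintf("  mean MAP posterior: %.3f\n", mean(object@posteriors)))
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf(
    "RawRecording: %d channel(s) x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(object@traces), ncol(object@traces), object@samplingRate,
    ncol(object@traces) / object@samplingRate,
    if (length(object@truthTimes))
      sprintf(", %d ground-truth spikes", length(object@truthTimes)) else ""
  ))
})
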