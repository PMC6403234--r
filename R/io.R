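#' Serialize a mixture model to JSON
#'
#' Writes weights, means (row-major), covariances and fit metadata at full
#' floating-point precision, so that [readModelJson()] restores a
#' bit-identical model.
#'
#' @param model a [MixtureModel-class].
#' @param path output file.
#' @export
writeModelJson <- function(model, path) {
  k <- length(model@weights)
  d <- ncol(model@means)
  obj <- list(
    n_components = k, dimension = d,
    weights = model@weights,
    means = as.numeric(t(model@means)), # row-major
    covariances = as.numeric(model@covariances),
    log_likelihood = model@logLik,
    log_likelihood_trace = model@logLikTrace,
    converged = model@converged,
    n_iterations = model@nIterations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeModelJson
#' @return `readModelJson` returns the restored [MixtureModel-class].
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$n_components
  d <- obj$dimension
  new("MixtureModel",
    weights = as.numeric(obj$weights),
    means = matrix(as.numeric(obj$means), nrow = k, ncol = d, byrow = TRUE),
    covariances = array(as.numeric(obj$covariances), dim = c(d, d, k)),
    logLik = as.numeric(obj$log_likelihood),
    logLikTrace = as.numeric(obj$log_likelihood_trace),
    converged = as.logical(obj$converged),
    nIterations = as.integer(obj$n_iterations),
    diagnostics = list()
  )
}

#' Write features in KlustaKwik .fet format
#'
#' Plain text: first line is the feature count, then one integer-scaled
#' feature row per spike. Values are scaled linearly so the largest
#' magnitude maps to `intScale`.
#'
#' @param features a [FeatureMatrix-class] or matrix.
#' @param path output file.
#' @param intScale integer full-scale (default 32000).
#' @export
writeFet <- function(features, path, intScale = 32000) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features) else
    as.matrix(features)
  mx <- max(abs(X))
  if (mx == 0) mx <- 1
  Xi <- round(X / mx * intScale)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(ncol(Xi)), con)
  utils::write.table(Xi, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write cluster labels in KlustaKwik .clu format
#'
#' Plain text: first line is the number of clusters, then one cluster id
#' per spike.
#'
#' @param result a [SortingResult-class] or an integer label vector.
#' @param path output file.
#' @export
writeClu <- function(result, path) {
  labels <- if (is(result, "SortingResult")) spikeLabels(result) else
    as.integer(result)
  writeLines(as.character(c(length(unique(labels)), labels)), path)
  invisible(path)
}

#' @rdname writeClu
#' @return `readClu` returns the integer label vector (the leading cluster
#'   count is dropped).
#' @export
readClu <- function(path) {
  v <- as.integer(readLines(path))
  v[-1L]
}

#' Write spike labels as CSV
#'
#' Two columns: spike index and cluster id.
#'
#' @inheritParams writeClu
#' @export
writeLabelsCsv <- function(result, path) {
  labels <- if (is(result, "SortingResult")) spikeLabels(result) else
    as.integer(result)
  utils::write.csv(
    data.frame(spike = seq_along(labels), cluster = labels),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Raw recording flat-binary I/O
#'
#' Writes traces as interleaved little-endian int16 with a JSON sidecar
#' (`<path>.json`) holding the channel count, sampling rate and the linear
#' scale factor used for quantization, plus ground truth (if any) as a CSV
#' (`<path>.truth.csv` with columns time, neuron). `readRawBinary` restores
#' the recording (amplitudes up to int16 quantization of about 1/32000 of
#' full scale).
#'
#' @param rec a [RawRecording-class].
#' @param path output file for the binary samples.
#' @export
writeRawBinary <- function(rec, path) {
  X <- rec@traces
  mx <- max(abs(X))
  scale <- if (mx == 0) 1 else mx / 32000
  Xi <- as.integer(round(X / scale)) # column order = interleaved channels
  writeBin(Xi, path, size = 2L, endian = "little")
  jsonlite::write_json(
    list(
      n_channels = nrow(X), n_samples = ncol(X),
      sampling_rate = rec@samplingRate, scale = scale,
      dtype = "int16", byte_order = "little", interleaved = TRUE
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  if (length(rec@truthTimes)) {
    utils::write.csv(
      data.frame(time = rec@truthTimes, neuron = rec@truthLabels),
      paste0(path, ".truth.csv"), row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname writeRawBinary
#' @return `readRawBinary` returns a [RawRecording-class].
#' @export
readRawBinary <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- hdr$n_channels * hdr$n_samples
  v <- readBin(path, "integer", n = n, size = 2L, signed = TRUE,
               endian = "little")
  X <- matrix(v * hdr$scale, nrow = hdr$n_channels)
  truthFile <- paste0(path, ".truth.csv")
  tt <- numeric(); tl <- integer()
  if (file.exists(truthFile)) {
    tr <- utils::read.csv(truthFile)
    tt <- tr$time
    tl <- as.integer(tr$neuron)
  }
  RawRecording(X, hdr$sampling_rate, truthTimes = tt, truthLabels = tl)
}

#' Waveform set CSV I/O
#'
#' Writes the waveform matrix with a small JSON sidecar holding the
#' sampling rate, channel layout and labels.
#'
#' @param wfs a [WaveformSet-class].
#' @param path output CSV file for the waveform matrix.
#' @export
writeWaveformsCsv <- function(wfs, path) {
  utils::write.table(waveforms(wfs), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(
      sampling_rate = samplingRate(wfs), n_channels = nChannels(wfs),
      spike_times = spikeTimes(wfs), true_labels = trueLabels(wfs)
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeWaveformsCsv
#' @return `readWaveformsCsv` returns a [WaveformSet-class].
#' @export
readWaveformsCsv <- function(path) {
  X <- as.matrix(utils::read.csv(path, header = FALSE))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  WaveformSet(
    X, hdr$sampling_rate, nChannels = hdr$n_channels,
    spikeTimes = if (length(hdr$spike_times)) hdr$spike_times else numeric(),
    trueLabels = if (length(hdr$true_labels)) hdr$true_labels else integer()
  )
}

#' Export feature values to CSV
#'
#' Header row carries the feature ids.
#'
#' @param features a [FeatureMatrix-class].
#' @param path output file.
#' @export
writeFeaturesCsv <- function(features, path) {
  X <- featureValues(features)
  colnames(X) <- featureInfo(features)$id
  utils::write.csv(X, path, row.names = FALSE)
  invisible(path)
}
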