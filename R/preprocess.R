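#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, applied per channel.
#' The default 300-3000 Hz band isolates the spike band and removes the
#' local-field/DC component.
#'
#' @param rec a [RawRecording-class].
#' @param low,high band edges in Hz (defaults 300 and 3000).
#' @param order Butterworth order of the one-pass filter (default 4; the
#'   forward-backward application doubles the effective order and cancels
#'   phase shift).
#' @return a [RawRecording-class] with filtered traces.
#' @export
bandpass <- function(rec, low = 300, high = 3000, order = 2L) {
  fs <- samplingRate(rec)
  nyq <- fs / 2
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= nyq)
    stop("high band edge (", high, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- rec@traces
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- signal::filtfilt(bf, rec@traces[ch, ])
  }
  new("RawRecording",
    traces = out, samplingRate = fs,
    truthTimes = rec@truthTimes, truthLabels = rec@truthLabels,
    metadata = c(rec@metadata, list(bandpass = c(low = low, high = high)))
  )
}

# robust (MAD-based) or plain per-channel SD
traceSd <- function(x, robust = TRUE) {
  if (robust) stats::mad(x, constant = 1.4826) else stats::sd(x)
}

#' Detect spikes by threshold crossing
#'
#' Applies a per-channel amplitude threshold of `thresholdSd` standard
#' deviations (robust, MAD-based by default, so large spikes do not inflate
#' the threshold) to the filtered traces. Each suprathreshold event is
#' centered at its local extremum and cut as a `window`-sample snippet per
#' channel; a refractory lockout prevents one event from being detected
#' twice. For multichannel groups the event time is the extremum across
#' channels and the per-channel snippets are concatenated in channel order.
#'
#' @param rec a (band-pass filtered) [RawRecording-class].
#' @param thresholdSd threshold in SD units, typically 3-7 (default 5).
#' @param window snippet length in samples per channel (even, default 64).
#' @param polarity "neg" (default; extracellular convention), "pos", or
#'   "both" (threshold on |x|).
#' @param lockoutMs refractory lockout between detections, ms (default 1).
#' @param suppressionRadius non-maximum suppression radius in samples
#'   (default: the window length). Band-pass filtering leaves an undershoot
#'   1-2 ms after a large trough that can re-cross the threshold outside the
#'   lockout; since two extrema within one snippet length describe the same
#'   event, only the largest detection within this radius is kept.
#' @param robustSd use MAD-based SD (default TRUE); FALSE for the plain SD.
#' @return a [WaveformSet-class]; `spikeTimes` holds the peak sample index
#'   of each detection. Zero detections yield an empty set with a warning.
#' @export
detectSpikes <- function(rec, thresholdSd = 5, window = 64L,
                         polarity = c("neg", "pos", "both"), lockoutMs = 1,
                         suppressionRadius = window, robustSd = TRUE) {
  polarity <- match.arg(polarity)
  window <- as.integer(window)
  if (window %% 2L != 0L) stop("window must be even")
  X <- rec@traces
  nCh <- nrow(X)
  nS <- ncol(X)
  if (window > nS) stop("window exceeds the trace length")
  if (!(thresholdSd >= 3 && thresholdSd <= 7))
    warning("thresholdSd outside the usual 3-7 SD range")

  sds <- apply(X, 1L, traceSd, robust = robustSd)
  # signed detection signal: most extreme channel in threshold units
  U <- X / sds
  detSig <- switch(polarity,
    neg = -apply(U, 2L, min),
    pos = apply(U, 2L, max),
    both = apply(abs(U), 2L, max)
  )
  over <- detSig > thresholdSd
  lockout <- max(1L, round(lockoutMs / 1000 * samplingRate(rec)))
  half <- window %/% 2L

  peaks <- integer()
  i <- 1L
  while (i <= nS) {
    if (over[i]) {
      # local extremum within the suprathreshold run (+ lockout look-ahead)
      jEnd <- min(nS, i + lockout)
      seg <- i:jEnd
      p <- seg[which.max(detSig[seg])]
      peaks <- c(peaks, p)
      i <- p + lockout
    } else {
      i <- i + 1L
    }
  }
  # non-maximum suppression: keep the largest detection within the radius
  if (length(peaks) > 1L && suppressionRadius > 0L) {
    ord <- peaks[order(detSig[peaks], decreasing = TRUE)]
    kept <- integer()
    for (p in ord) {
      if (!length(kept) || min(abs(kept - p)) >= suppressionRadius)
        kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  # drop events whose window would cross the trace boundary
  peaks <- peaks[peaks - half + 1L >= 1L & peaks + half <= nS]
  if (!length(peaks)) {
    warning("no spikes detected")
    return(WaveformSet(
      matrix(numeric(), 0L, nCh * window), samplingRate(rec),
      nChannels = nCh,
      metadata = list(thresholdSd = thresholdSd, polarity = polarity,
                      channelOrder = seq_len(nCh))
    ))
  }
  wf <- t(vapply(peaks, function(p) {
    idx <- (p - half + 1L):(p + half)
    unlist(lapply(seq_len(nCh), function(ch) X[ch, idx]), use.names = FALSE)
  }, numeric(nCh * window)))
  WaveformSet(
    wf, samplingRate(rec), nChannels = nCh, spikeTimes = as.numeric(peaks),
    metadata = list(
      thresholdSd = thresholdSd, polarity = polarity,
      lockoutMs = lockoutMs, robustSd = robustSd, window = window,
      channelOrder = seq_len(nCh), channelSd = sds
    )
  )
}

#' Label detections from ground-truth spike times
#'
#' Matches each ground-truth event to detected spikes within `toleranceMs`
#' (default 2 ms). A truth event with exactly one candidate transfers its
#' label to that detection; a truth event with more than one candidate in
#' the window is ambiguous and discarded; one with none is a miss.
#' Unmatched detections are labeled 0 (background).
#'
#' @param wfs a [WaveformSet-class] with `spikeTimes` set.
#' @param truthTimes ground-truth peak sample indices (same clock as
#'   `spikeTimes(wfs)`).
#' @param truthLabels integer neuron id per truth time (default all 1).
#' @param toleranceMs matching window, ms (default 2).
#' @return the [WaveformSet-class] with `trueLabels` filled; matching
#'   diagnostics (`nMatched`, `nMissed`, `nAmbiguous`) are stored in
#'   `metadata$groundTruth`.
#' @export
matchGroundTruth <- function(wfs, truthTimes,
                             truthLabels = rep(1L, length(truthTimes)),
                             toleranceMs = 2) {
  st <- spikeTimes(wfs)
  if (!length(st)) stop("WaveformSet has no spike times to match against")
  tol <- toleranceMs / 1000 * samplingRate(wfs)
  labels <- rep(0L, nSpikes(wfs))
  nMissed <- 0L
  nAmbiguous <- 0L
  for (i in seq_along(truthTimes)) {
    dd <- abs(st - truthTimes[i])
    cand <- which(dd <= tol)
    if (length(cand) == 0L) {
      nMissed <- nMissed + 1L
    } else if (length(cand) > 1L) {
      nAmbiguous <- nAmbiguous + 1L
    } else {
      labels[cand] <- as.integer(truthLabels[i])
    }
  }
  out <- wfs
  out@trueLabels <- labels
  out@metadata$groundTruth <- list(
    nTruth = length(truthTimes),
    nMatched = sum(labels > 0L), nMissed = nMissed, nAmbiguous = nAmbiguous,
    toleranceMs = toleranceMs
  )
  validObject(out)
  out
}
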