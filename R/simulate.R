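#' Simulation specification
#'
#' Parameters of a synthetic extracellular recording: a few target neurons
#' with distinct template waveforms and controllable signal-to-noise ratio,
#' superimposed on background activity made of many low-amplitude spikes
#' from other templates plus Gaussian noise. The structure mirrors simulated
#' benchmark recordings in which three known waveforms are added to ~60 s of
#' background activity at random times.
#'
#' @param nTargetNeurons number of ground-truth neurons (default 3).
#' @param duration recording length in seconds (default 60).
#' @param samplingRate Hz (default 24000).
#' @param templateBankSize number of parametric template shapes in the bank
#'   (default 24; targets are drawn from it, the rest feed the background).
#' @param snr per-neuron peak amplitude over background-noise SD (recycled;
#'   default `c(6, 9, 12)`, mirroring target neurons superimposed at
#'   different signal-to-noise ratios).
#' @param firingRates Hz per neuron (recycled; default 5).
#' @param backgroundRate rate of background spikes in Hz (default 20).
#' @param backgroundAmplitude peak amplitude of background spikes relative
#'   to the Gaussian noise SD (default 1.5, i.e. below detection threshold).
#' @param outlierFraction probability that a target spike is made a
#'   coincident-spike outlier (a second target spike forced within 0.5 ms,
#'   waveforms summed; default 0).
#' @param templateSamples template support in samples (default 64).
#' @param minTemplateDistance minimum pairwise L2 distance between target
#'   templates (peak-normalized units; default 0.5).
#' @param refractoryMs per-neuron refractory period, ms (default 2).
#' @param seed integer seed; the whole simulation is a pure function of the
#'   spec including this seed.
#' @return a list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nTargetNeurons = 3L, duration = 60,
                           samplingRate = 24000, templateBankSize = 24L,
                           snr = c(6, 9, 12), firingRates = 5, backgroundRate = 20,
                           backgroundAmplitude = 1.5, outlierFraction = 0,
                           templateSamples = 64L, minTemplateDistance = 0.5,
                           refractoryMs = 2, seed = 1L) {
  spec <- list(
    nTargetNeurons = as.integer(nTargetNeurons), duration = duration,
    samplingRate = samplingRate,
    templateBankSize = as.integer(templateBankSize),
    snr = rep_len(snr, nTargetNeurons),
    firingRates = rep_len(firingRates, nTargetNeurons),
    backgroundRate = backgroundRate,
    backgroundAmplitude = backgroundAmplitude,
    outlierFraction = outlierFraction,
    templateSamples = as.integer(templateSamples),
    minTemplateDistance = minTemplateDistance,
    refractoryMs = refractoryMs, seed = as.integer(seed)
  )
  stopifnot(
    spec$nTargetNeurons >= 1L, spec$duration > 0, spec$samplingRate > 0,
    spec$templateBankSize >= spec$nTargetNeurons,
    all(spec$snr > 0), all(spec$firingRates > 0), spec$backgroundRate > 0,
    spec$outlierFraction >= 0, spec$outlierFraction <= 1
  )
  if (spec$duration * min(spec$firingRates) < 50)
    warning("fewer than 50 expected spikes for the sparsest neuron; ",
            "clustering may be unreliable")
  class(spec) <- "SimulationSpec"
  spec
}

# one parametric extracellular template: a sharp negative trough with an
# optional pre-spike positivity and a slower after-hyperpolarization bump;
# peak-normalized so that max |w| = 1 (at the trough)
parametricTemplate <- function(nSamples, fs, troughSdMs, ahpRatio, ahpDelayMs,
                               ahpWidthFactor, preRatio) {
  tc <- (nSamples / 2) / fs * 1000 # trough at the center sample, ms
  t <- (seq_len(nSamples) - 0.5) / fs * 1000
  w <- -exp(-(t - tc)^2 / (2 * troughSdMs^2)) +
    ahpRatio * exp(-(t - tc - ahpDelayMs)^2 /
                     (2 * (troughSdMs * ahpWidthFactor)^2)) +
    preRatio * exp(-(t - tc + 2 * troughSdMs)^2 / (2 * (troughSdMs / 1.5)^2))
  w / max(abs(w))
}

#' Generate a bank of spike templates
#'
#' Draws `templateBankSize` parametric biphasic/triphasic waveform shapes
#' with randomized trough width (spanning roughly 0.3-1.2 ms full width),
#' after-hyperpolarization amplitude/latency and pre-spike positivity, each
#' peak-normalized to amplitude 1 at the trough (negative, extracellular
#' convention). The first `nTargetNeurons` templates are the targets; they
#' are rejection-sampled until every target pair is at least
#' `minTemplateDistance` apart in L2 norm, so target shapes are genuinely
#' distinct. The remaining templates feed the background.
#'
#' @param spec a [simulationSpec()].
#' @return templates x samples matrix; row i is template i.
#' @export
makeTemplateBank <- function(spec) {
  set.seed(childSeed(spec$seed, 1L))
  nS <- spec$templateSamples
  fs <- spec$samplingRate
  drawOne <- function() {
    # rejection: the trough must dominate (extracellular convention), so the
    # normalized template has its unit peak at the trough
    repeat {
      w <- parametricTemplate(
        nS, fs,
        troughSdMs = stats::runif(1, 0.064, 0.26),
        ahpRatio = stats::runif(1, 0.25, 0.7),
        ahpDelayMs = stats::runif(1, 0.3, 0.8),
        ahpWidthFactor = stats::runif(1, 1.2, 2.5),
        preRatio = stats::runif(1, 0, 0.25)
      )
      if (max(w) < 0.9) return(w) # trough is the unit peak
    }
  }
  nT <- spec$nTargetNeurons
  targets <- matrix(NA_real_, nT, nS)
  accepted <- 0L
  tries <- 0L
  while (accepted < nT) {
    tries <- tries + 1L
    if (tries > 5000L) stop("could not draw sufficiently distinct templates; ",
                            "lower minTemplateDistance")
    cand <- drawOne()
    ok <- accepted == 0L ||
      all(sqrt(rowSums(sweep(targets[seq_len(accepted), , drop = FALSE],
                             2L, cand)^2)) >= spec$minTemplateDistance)
    if (ok) {
      accepted <- accepted + 1L
      targets[accepted, ] <- cand
    }
  }
  nRest <- spec$templateBankSize - nT
  rest <- if (nRest > 0L) {
    t(vapply(seq_len(nRest), function(i) drawOne(), numeric(nS)))
  } else {
    matrix(numeric(), 0L, nS)
  }
  rbind(targets, rest)
}

poissonTrainWithRefractory <- function(rate, duration, fs, refractoryMs) {
  # thinning-free: draw exponential gaps, enforce the refractory floor
  refr <- refractoryMs / 1000
  times <- numeric()
  t <- 0
  repeat {
    t <- t + stats::rexp(1L, rate) + refr
    if (t > duration) break
    times <- c(times, t)
  }
  round(times * fs)
}

#' Synthesize a recording or a labeled waveform set
#'
#' `output = "recording"` builds the full continuous trace: background
#' spikes drawn from the non-target templates at low amplitude plus white
#' Gaussian noise, with each target neuron's spikes (Poisson train with a
#' refractory period) added at an amplitude of `snr` times the measured
#' background SD. Ground-truth trough times and labels are recorded.
#' Optional coincident-spike outliers superimpose a second target's waveform
#' within 0.5 ms of a target spike.
#'
#' `output = "waveforms"` skips the continuous trace and emits the labeled
#' [WaveformSet-class] directly: template plus unit-SD background noise per
#' snippet, amplitude `snr`. This is the fast path for experiments that do
#' not exercise detection.
#'
#' @param spec a [simulationSpec()].
#' @param output "recording" or "waveforms".
#' @return a [RawRecording-class] or a [WaveformSet-class].
#' @export
synthesize <- function(spec, output = c("recording", "waveforms")) {
  output <- match.arg(output)
  bank <- makeTemplateBank(spec)
  nT <- spec$nTargetNeurons
  nS <- spec$templateSamples
  fs <- spec$samplingRate
  set.seed(childSeed(spec$seed, 2L))

  if (output == "waveforms") {
    counts <- stats::rpois(nT, spec$firingRates * spec$duration)
    counts <- pmax(counts, 1L)
    labels <- rep(seq_len(nT), counts)
    wf <- matrix(stats::rnorm(sum(counts) * nS), ncol = nS)
    for (j in seq_len(nT)) {
      rows <- which(labels == j)
      wf[rows, ] <- wf[rows, , drop = FALSE] +
        matrix(spec$snr[j] * bank[j, ], length(rows), nS, byrow = TRUE)
    }
    ord <- sample.int(length(labels)) # interleave neurons
    return(WaveformSet(
      wf[ord, , drop = FALSE], fs, nChannels = 1L,
      trueLabels = labels[ord],
      metadata = list(simulationSpec = unclass(spec), mode = "waveforms")
    ))
  }

  nSamples <- round(spec$duration * fs)
  half <- nS %/% 2L
  addSpike <- function(trace, at, w, amp) {
    # 'at' is the trough sample; template trough sits at index half
    idx <- (at - half + 1L):(at - half + nS)
    ok <- idx >= 1L & idx <= nSamples
    trace[idx[ok]] <- trace[idx[ok]] + amp * w[ok]
    trace
  }

  # background: Gaussian noise (unit SD) + low-amplitude off-target spikes
  trace <- stats::rnorm(nSamples)
  nBg <- stats::rpois(1L, spec$backgroundRate * spec$duration)
  if (nrow(bank) > nT && nBg > 0L) {
    bgTimes <- sample.int(nSamples, nBg, replace = TRUE)
    bgTpl <- sample((nT + 1L):nrow(bank), nBg, replace = TRUE)
    bgAmp <- spec$backgroundAmplitude * stats::runif(nBg, 0.5, 1.5)
    for (b in seq_len(nBg)) {
      trace <- addSpike(trace, bgTimes[b], bank[bgTpl[b], ], bgAmp[b])
    }
  }
  bgSd <- stats::sd(trace)

  truthTimes <- numeric()
  truthLabels <- integer()
  outlierFlag <- logical()
  margin <- nS # keep spikes clear of the trace boundary
  for (j in seq_len(nT)) {
    tt <- poissonTrainWithRefractory(spec$firingRates[j], spec$duration, fs,
                                     spec$refractoryMs)
    tt <- tt[tt > margin & tt < nSamples - margin]
    amp <- spec$snr[j] * bgSd
    for (at in tt) {
      trace <- addSpike(trace, at, bank[j, ], amp)
    }
    truthTimes <- c(truthTimes, tt)
    truthLabels <- c(truthLabels, rep(j, length(tt)))
    outlierFlag <- c(outlierFlag, rep(FALSE, length(tt)))
  }
  # coincident-spike outliers: a second target within 0.5 ms (waveforms sum)
  if (spec$outlierFraction > 0 && nT >= 2L) {
    isOut <- stats::runif(length(truthTimes)) < spec$outlierFraction
    for (i in which(isOut)) {
      other <- sample(setdiff(seq_len(nT), truthLabels[i]), 1L)
      shift <- sample.int(max(1L, round(0.0005 * fs)), 1L)
      at2 <- truthTimes[i] + shift
      trace <- addSpike(trace, at2, bank[other, ], spec$snr[other] * bgSd)
      outlierFlag[i] <- TRUE
    }
  }
  ord <- order(truthTimes)
  RawRecording(
    matrix(trace, nrow = 1L), fs,
    truthTimes = truthTimes[ord], truthLabels = truthLabels[ord],
    metadata = list(
      simulationSpec = unclass(spec), backgroundSd = bgSd,
      templateBank = bank, outlier = outlierFlag[ord],
      targetAmplitudes = spec$snr * bgSd
    )
  )
}

#' Subsample one class to a symmetry index
#'
#' First equalizes all true classes to the minimum class count (random
#' subsample without replacement), then subsamples the target class to
#' `index` percent of that count (rounded, at least 1 spike). Background
#' (label 0) spikes are left untouched.
#'
#' @param wfs a labeled [WaveformSet-class].
#' @param targetClass the true class to subsample.
#' @param index symmetry index in percent, in (0, 100].
#' @param seed integer seed.
#' @return a [WaveformSet-class].
#' @export
subsampleForSymmetry <- function(wfs, targetClass, index, seed = 1L) {
  if (index <= 0 || index > 100) stop("index must be in (0, 100]")
  labs <- trueLabels(wfs)
  if (!length(labs)) stop("WaveformSet has no true labels")
  classes <- sort(unique(labs[labs > 0L]))
  if (!targetClass %in% classes) stop("targetClass not present")
  set.seed(seed)
  minCount <- min(table(labs[labs > 0L]))
  keep <- integer()
  for (cl in classes) {
    rows <- which(labs == cl)
    rows <- sort(sample(rows, minCount))
    if (cl == targetClass) {
      nKeep <- max(1L, round(index / 100 * minCount))
      rows <- sort(sample(rows, nKeep))
    }
    keep <- c(keep, rows)
  }
  keep <- sort(c(keep, which(labs == 0L)))
  if (!length(keep)) stop("subsampling produced an empty waveform set")
  WaveformSet(
    waveforms(wfs)[keep, , drop = FALSE], samplingRate(wfs),
    nChannels = nChannels(wfs),
    spikeTimes = if (length(spikeTimes(wfs))) spikeTimes(wfs)[keep] else
      numeric(),
    trueLabels = labs[keep],
    metadata = c(wfs@metadata,
                 list(symmetry = list(targetClass = targetClass,
                                      index = index, seed = seed)))
  )
}
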