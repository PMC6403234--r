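# FFT gain of a filtered sinusoid relative to the input
sineGain <- function(freq, fs = 24000, dur = 1) {
  t <- seq(0, dur, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  rec <- RawRecording(matrix(x, 1), fs)
  y <- traces(bandpass(rec))[1, ]
  core <- seq(round(0.1 * fs), round(0.9 * fs)) # avoid edge transients
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}

test_that("band-pass keeps the passband and rejects hum and DC", {
  expect_gt(sineGain(1000), 0.95)
  expect_lt(sineGain(1000), 1.05)
  expect_lt(sineGain(50), 0.1) # >= 20 dB down
  # DC is rejected (away from the forward-backward edge transients)
  rec <- RawRecording(matrix(rep(2, 24000), 1), 24000)
  expect_lt(max(abs(traces(bandpass(rec))[1, 2000:22000])), 1e-6)
  expect_error(bandpass(RawRecording(matrix(rnorm(100), 1), 4000)),
               "Nyquist")
  expect_error(bandpass(RawRecording(matrix(rnorm(100), 1), 24000),
                        low = 0), "low")
})

test_that("threshold detection finds exactly the injected spikes, aligned at center", {
  set.seed(42)
  fs <- 24000
  x <- rnorm(fs) # 1 s of unit noise
  at <- sort(sample(seq(2000, fs - 2000, by = 1200), 10))
  x[at] <- x[at] - 10 # 10 SD negative events
  rec <- RawRecording(matrix(x, 1), fs)
  wfs <- detectSpikes(rec, thresholdSd = 5)
  expect_identical(nSpikes(wfs), 10L)
  expect_true(all(abs(spikeTimes(wfs) - at) <= 1))
  # every snippet's extremum sits at the center sample
  mins <- apply(waveforms(wfs), 1, which.min)
  expect_true(all(mins == 32L))
})

test_that("threshold above the signal yields zero detections, with a warning", {
  set.seed(43)
  rec <- RawRecording(matrix(rnorm(24000), 1), 24000)
  expect_warning(wfs <- detectSpikes(rec, thresholdSd = 7), "no spikes")
  expect_identical(nSpikes(wfs), 0L)
})

test_that("two events inside the suppression window yield one detection", {
  set.seed(44)
  fs <- 24000
  x <- rnorm(fs) * 0.1
  p <- 12000
  x[p] <- -10
  x[p + round(0.0005 * fs)] <- -8 # 0.5 ms later
  rec <- RawRecording(matrix(x, 1), fs)
  wfs <- detectSpikes(rec, thresholdSd = 5)
  expect_identical(nSpikes(wfs), 1L)
  expect_identical(spikeTimes(wfs), as.numeric(p))
})

test_that("detection recall on high-SNR spikes is perfect at 5 SD", {
  fs <- 24000
  hits <- sapply(1:25, function(r) {
    set.seed(900 + r)
    x <- rnorm(fs / 2)
    at <- sort(sample(seq(1000, fs / 2 - 1000, by = 600), 8))
    for (p in at) x[p] <- x[p] - 9 # 9 SD events
    wfs <- detectSpikes(RawRecording(matrix(x, 1), fs), thresholdSd = 5)
    sum(sapply(at, function(p) any(abs(spikeTimes(wfs) - p) <= 2)))
  })
  expect_identical(sum(hits), 25L * 8L)
})

test_that("tetrode snippets concatenate channels in recorded order", {
  set.seed(45)
  fs <- 24000
  X <- matrix(rnorm(4 * fs) * 0.5, 4)
  p <- 10000
  X[2, p] <- -12 # spike on channel 2 only
  wfs <- detectSpikes(RawRecording(X, fs), thresholdSd = 5)
  expect_identical(nSpikes(wfs), 1L)
  expect_identical(nChannels(wfs), 4L)
  expect_identical(ncol(waveforms(wfs)), 256L)
  seg <- waveforms(wfs)[1, 65:128] # channel 2 segment
  expect_equal(min(seg), -12, tolerance = 1e-12)
  expect_identical(wfs@metadata$channelOrder, 1:4)
})

test_that("ground-truth matching applies the 2 ms ambiguity rule", {
  fs <- 24000
  wfs <- WaveformSet(matrix(rnorm(5 * 64), 5), fs,
                     spikeTimes = c(1000, 1012, 5000, 9000, 20000))
  ms <- fs / 1000
  truth <- c(1000 + 0.5 * ms,  # two candidates within 2 ms -> ambiguous
             5000 + 0.5 * ms,  # single candidate -> matched
             9000 + 3 * ms,    # outside tolerance -> miss
             20000)            # exact -> matched
  out <- matchGroundTruth(wfs, truth, truthLabels = c(1L, 2L, 3L, 1L))
  expect_identical(trueLabels(out), c(0L, 0L, 2L, 0L, 1L))
  gt <- out@metadata$groundTruth
  expect_identical(gt$nAmbiguous, 1L)
  expect_identical(gt$nMissed, 1L)
  expect_identical(gt$nMatched, 2L)
})

test_that("robust SD resists spike contamination", {
  set.seed(46)
  x <- rnorm(10000)
  x[seq(100, 10000, by = 100)] <- -40
  expect_lt(abs(gmmsort:::traceSd(x, robust = TRUE) - 1), 0.05)
  expect_gt(gmmsort:::traceSd(x, robust = FALSE), 2)
})
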