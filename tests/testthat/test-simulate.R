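test_that("the template bank is reproducible, normalized, and distinct", {
  spec <- simulationSpec(duration = 10, seed = 12)
  a <- makeTemplateBank(spec)
  b <- makeTemplateBank(spec)
  expect_identical(a, b)
  expect_identical(nrow(a), spec$templateBankSize)
  expect_equal(apply(abs(a), 1, max), rep(1, nrow(a)), tolerance = 1e-12)
  # negative trough convention
  expect_true(all(apply(a, 1, min) == -1))
  targets <- a[1:3, ]
  dists <- dist(targets)
  expect_gte(min(dists), spec$minTemplateDistance)
})

test_that("the simulation is a pure function of its spec", {
  spec <- simulationSpec(duration = 5, firingRates = 12, seed = 33)
  expect_warning(r1 <- synthesize(spec), NA)
  r2 <- synthesize(spec)
  expect_identical(traces(r1), traces(r2))
  expect_identical(truthTimes(r1), truthTimes(r2))
  w1 <- synthesize(spec, "waveforms")
  w2 <- synthesize(spec, "waveforms")
  expect_identical(waveforms(w1), waveforms(w2))
})

test_that("injected amplitudes calibrate to the requested SNR", {
  spec <- simulationSpec(duration = 10, firingRates = 8, snr = c(5, 8, 12),
                         seed = 21)
  rec <- synthesize(spec)
  amp <- rec@metadata$targetAmplitudes
  expect_equal(amp / rec@metadata$backgroundSd, c(5, 8, 12),
               tolerance = 1e-12)
  # empirical: measured trough amplitude at the truth samples over the
  # background SD; the median across spikes cancels background fluctuation
  # up to overlap contamination from neighboring spikes
  tr <- traces(rec)[1, ]
  for (j in 1:3) {
    tt <- truthTimes(rec)[truthLabels(rec) == j]
    troughs <- -sapply(tt, function(p) tr[p])
    expect_lt(abs(median(troughs) / rec@metadata$backgroundSd - spec$snr[j]),
              0.1 * spec$snr[j])
  }
})

test_that("truth bookkeeping respects the refractory period", {
  spec <- simulationSpec(duration = 30, firingRates = 20, seed = 9)
  rec <- synthesize(spec)
  for (j in 1:3) {
    tt <- sort(truthTimes(rec)[truthLabels(rec) == j])
    expect_true(all(diff(tt) >= spec$refractoryMs / 1000 * spec$samplingRate))
  }
  expect_identical(length(truthTimes(rec)), length(truthLabels(rec)))
})

test_that("coincident-spike outliers are injected and flagged", {
  spec <- simulationSpec(duration = 20, firingRates = 10,
                         outlierFraction = 0.1, seed = 14)
  rec <- synthesize(spec)
  flags <- rec@metadata$outlier
  expect_identical(length(flags), length(truthTimes(rec)))
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.25)
})

test_that("zero-information waveforms give MI_norm near zero", {
  # snr -> 0: waveforms are pure noise, labels carry no information
  spec <- simulationSpec(duration = 10, firingRates = 15, snr = 1e-6,
                         seed = 4)
  wfs <- synthesize(spec, "waveforms")
  res <- sortSpikes(wfs, method = "pca", metric = "var",
                    options = quickOpts(nReplicates = 2), seed = 2)
  mi <- miNorm(contingencyTable(trueLabels(wfs), spikeLabels(res)))
  expect_lt(mi, 5)
})

test_that("raw simulation output round-trips through the binary format for preprocessing", {
  spec <- simulationSpec(duration = 5, firingRates = 15, seed = 8)
  rec <- synthesize(spec)
  path <- file.path(tempdir(), "sim.dat")
  writeRawBinary(rec, path)
  back <- readRawBinary(path)
  expect_identical(truthTimes(back), truthTimes(rec))
  expect_identical(truthLabels(back), truthLabels(rec))
  expect_lt(max(abs(traces(back) - traces(rec))) / max(abs(traces(rec))),
            1e-4)
})
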