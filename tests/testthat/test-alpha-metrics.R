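test_that("IAF detection finds a Gaussian peak on a 1/f background", {
  ps <- syntheticSpectrum(peakHz = 10, peakAmp = 6, peakSd = 1)
  ## oracle: argmax of the background-subtracted spectrum
  freqs <- ps@freqs
  resid <- colMeans(ps@values) - 5 / freqs
  oracle <- freqs[which.max(resid)]
  expect_equal(oracle, 10)
  expect_equal(detectIAF(ps), 10)
})

test_that("spectra without curvature maxima report no peak", {
  ## exact cubic polynomial: the second gradient is linear, the SG filter
  ## reproduces it exactly, and a linear function has no interior maximum
  freqs <- seq(0.5, 40, by = 0.5)
  vals <- 1e-3 * (45 - freqs)^3 + 5
  ps <- new("PowerSpectrum", freqs = freqs,
            values = matrix(vals, 1, byrow = TRUE), scale = "raw",
            channels = "ch01")
  iaf <- detectIAF(ps)
  expect_true(is.na(iaf))
  expect_equal(attr(iaf, "reason"), "no peak")
})

test_that("ties between equal peaks break toward the lower frequency", {
  ## peaks separated by more than the 5 Hz smoothing window so the
  ## curvature transform keeps them distinct; the spectrum is symmetric
  ## about 10 Hz, making the two smoothed maxima exactly tied
  freqs <- seq(0.5, 40, by = 0.5)
  vals <- 1 + 4 * exp(-(freqs - 8)^2 / 0.5) + 4 * exp(-(freqs - 12)^2 / 0.5)
  ps <- new("PowerSpectrum", freqs = freqs,
            values = matrix(vals, 1, byrow = TRUE), scale = "raw",
            channels = "ch01")
  expect_equal(detectIAF(ps), 8)
  ## peaks closer than the smoothing window merge at their midpoint
  vals2 <- 1 + 4 * exp(-(freqs - 9)^2 / 0.5) + 4 * exp(-(freqs - 11)^2 / 0.5)
  ps2 <- new("PowerSpectrum", freqs = freqs,
             values = matrix(vals2, 1, byrow = TRUE), scale = "raw",
             channels = "ch01")
  expect_equal(detectIAF(ps2), 10)
})

test_that("high-SNR detection agrees with the naive spectral argmax", {
  for (s in 1:20) {
    peak <- withSeed(s, runif(1, 8, 13))
    ps <- syntheticSpectrum(peakHz = peak, peakAmp = 10, noiseSd = 0.02,
                            seed = s)
    avg <- colMeans(ps@values)
    win <- ps@freqs >= 6 & ps@freqs <= 14
    naive <- ps@freqs[win][which.max(avg[win])]
    expect_equal(detectIAF(ps), naive)
  }
})

test_that("IAF recovery stays within one grid step under noise", {
  hits <- 0
  n <- 60
  for (s in 1:n) {
    truth <- withSeed(1000 + s, runif(1, 8, 13))
    ps <- syntheticSpectrum(peakHz = truth, peakAmp = 6, noiseSd = 0.1,
                            seed = 2000 + s)
    est <- detectIAF(ps)
    if (!is.na(est) && abs(est - truth) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("IAP averages the five grid points around the IAF", {
  freqs <- seq(0.5, 40, by = 0.5)
  flat <- new("PowerSpectrum", freqs = freqs,
              values = matrix(-3, 1, length(freqs)), scale = "dB",
              channels = "ch01")
  expect_equal(computeIAP(flat, 10), -3)
  vals <- rep(0, length(freqs))
  vals[freqs >= 9 & freqs <= 11] <- c(1, 2, 3, 2, 1)
  ps <- new("PowerSpectrum", freqs = freqs,
            values = matrix(vals, 1, byrow = TRUE), scale = "dB",
            channels = "ch01")
  expect_equal(computeIAP(ps, 10), 1.8)
  ## shifting the whole spectrum shifts the IAP by the same amount
  ps2 <- ps
  ps2@values <- ps@values + 2.5
  expect_equal(computeIAP(ps2, 10), computeIAP(ps, 10) + 2.5)
  ## band extending beyond the spectrum is an error
  expect_error(computeIAP(ps, 39.8), "beyond")
  expect_error(computeIAP(toRawPower(ps), 10), "log-power")
})

test_that("lateralization index is contra minus ipsi", {
  expect_equal(lateralizationIndex(-4, -2), -2)
  expect_error(lateralizationIndex(NA, -2), "missing")
  ## generator arithmetic: +/-2 dB per side gives about -4 dB
  m <- testMontage(16)
  sides <- rep(c("left", "right"), 4)
  trials <- lapply(1:8, function(k)
    generateTrial(stimulusBand("alpha"), attendedSide = sides[k],
                  seed = k))
  sp <- subjectParams(iafTrue = 10, alphaAmp = 6, attnModulation = 2,
                      noiseAmp = 0.3)
  rec <- simulateRecording(sp, trials, m, seed = 31)
  ep <- epochData(rec, excludeEventTrials = FALSE)
  lat <- vapply(c("left", "right"), function(side) {
    idx <- which(ep@info$attendedSide == side)
    ps <- toLogPower(powerSpectrum(alphakit:::subsetEpochs(ep, idx)))
    contra <- if (side == "left") rightCluster(m) else leftCluster(m)
    ipsi <- if (side == "left") leftCluster(m) else rightCluster(m)
    lateralizationIndex(computeIAP(ps, 10, contra),
                        computeIAP(ps, 10, ipsi))
  }, 0)
  expect_equal(mean(lat), -4, tolerance = 1.2)
})

test_that("phase-locking value spans its theoretical anchors", {
  fs <- 256
  n <- fs * 2
  t <- (0:(n - 1)) / fs
  phase <- 2 * pi * 10 * t
  eeg <- matrix(sin(phase), 1, byrow = TRUE)
  expect_equal(phaseLockingValue(eeg, phase, c(8, 12), fs), 1,
               tolerance = 0.02)
  ## independent noise epochs: E[PLV] ~ sqrt(pi / (4 nEpochs))
  nEp <- 16
  plvs <- vapply(1:8, function(s) {
    noise <- withSeed(700 + s, matrix(rnorm(nEp * n), nEp, n))
    phaseLockingValue(noise, matrix(phase, nEp, n, byrow = TRUE),
                      c(8, 12), fs)
  }, 0)
  expect_equal(mean(plvs), sqrt(pi / (4 * nEp)), tolerance = 0.1)
  expect_error(phaseLockingValue(eeg, phase, c(12, 8), fs), "degenerate")
})

test_that("stimulus-locked drive raises in-band phase locking", {
  m <- testMontage(16)
  trials <- lapply(1:4, function(k)
    generateTrial(stimulusBand("alpha"), attendedSide = "left", seed = k))
  sp <- subjectParams(iafTrue = 10, alphaAmp = 1, driveSnr = 3,
                      attnModulation = 0, noiseAmp = 0.5)
  rec <- simulateRecording(sp, trials, m, seed = 17)
  fs <- rec@fs
  stimSamp <- round(3.5 * fs)
  ch <- match(leftCluster(m)[1], channelLabels(m))
  eeg <- t(vapply(seq_along(trials), function(k)
    rec@data[ch, rec@onsets[k]:(rec@onsets[k] + stimSamp - 1)],
    numeric(stimSamp)))
  phases <- t(vapply(seq_along(trials), function(k)
    alphakit:::resamplePhase(trials[[k]]@cmfLeft, fs, stimSamp),
    numeric(stimSamp)))
  inBand <- phaseLockingValue(eeg, phases, c(8, 13), fs)
  offBand <- phaseLockingValue(eeg, phases, c(18, 24), fs)
  expect_gt(inBand, offBand)
})
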