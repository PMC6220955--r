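test_that("FM trajectories respect band, rate limit and determinism", {
  for (bandName in c("theta", "alpha", "beta")) {
    band <- stimulusBand(bandName)
    bw <- bandwidth(band)
    for (seed in 1:50) {
      fm <- generateFMFunction(band, duration = 3.5, frameRate = 100,
                               seed = seed)
      f <- fmFrequencies(fm)
      expect_length(f, 350)
      expect_true(all(f >= band@fLo - 1e-9 & f <= band@fHi + 1e-9))
      expect_lte(max(abs(diff(f))) * 100, bw + 1e-9)
    }
  }
  fm1 <- generateFMFunction(stimulusBand("theta"), seed = 42)
  fm2 <- generateFMFunction(stimulusBand("theta"), seed = 42)
  fm3 <- generateFMFunction(stimulusBand("theta"), seed = 43)
  expect_identical(fmFrequencies(fm1), fmFrequencies(fm2))
  expect_false(all(fmFrequencies(fm1) == fmFrequencies(fm3)))
})

test_that("degenerate zero-bandwidth band gives a constant trajectory", {
  fm <- generateFMFunction(stimulusBand("const", 10, 10), duration = 1,
                           seed = 1)
  expect_true(all(fmFrequencies(fm) == 10))
})

test_that("invalid FM parameters raise errors", {
  expect_error(generateFMFunction(stimulusBand("theta"), duration = 0),
               "duration")
  expect_error(generateFMFunction(stimulusBand("theta"), frameRate = -1),
               "frameRate")
})

test_that("contrast timecourse integrates phase and maps luminance", {
  fm <- generateFMFunction(stimulusBand("const", 10, 10), duration = 1,
                           seed = 1)
  cmf <- fmToCMF(fm, phase0 = 0)
  ## constant 10 Hz over 1 s: phase advances 10 cycles
  nominal <- (cmf@phase[length(cmf@phase)] - cmf@phase[1]) +
    2 * pi * 10 / 100  # add the final frame's increment
  expect_equal(nominal / (2 * pi), 10, tolerance = 1e-6)
  ## phase0 = pi/2 starts at the luminance maximum
  cmf2 <- fmToCMF(fm, phase0 = pi / 2)
  expect_equal(cmf2@luminance[1], 29.1, tolerance = 1e-9)
  ## bounds are attained within the sampling tolerance and never exceeded
  band <- stimulusBand("alpha")
  for (seed in 1:10) {
    cm <- fmToCMF(generateFMFunction(band, seed = seed),
                  phase0 = seed)
    expect_true(all(cm@luminance >= 7.5 - 1e-9 &
                    cm@luminance <= 29.1 + 1e-9))
    tol <- (29.1 - 7.5) * (1 - cos(pi * 13 / 100)) / 2 + 1e-6
    expect_lte(min(cm@luminance), 7.5 + tol)
    expect_gte(max(cm@luminance), 29.1 - tol)
    expect_true(all(diff(cm@phase) > 0))
  }
  expect_error(fmToCMF(fm, lumMin = 30, lumMax = 29.1), "lumMin")
})

test_that("decorrelated pairs meet the correlation bound", {
  band <- stimulusBand("alpha")
  rs <- vapply(1:40, function(s)
    generateDecorrelatedPair(band, seed = s)$r, 0)
  expect_true(all(abs(rs) < 0.05))
  ## vacuous constraint accepts the first candidate
  expect_equal(generateDecorrelatedPair(band, rMax = 0.999,
                                        seed = 1)$tries, 1L)
  ## identical member seeds can never decorrelate
  expect_error(
    generateDecorrelatedPair(band, seed = 1, maxTries = 3,
                             seedLeft = 5L, seedRight = 5L),
    "not achieved")
})

test_that("event placement matches the occurrence and spacing rules", {
  ev <- placeEvents(3000, seed = 11)
  counts <- vapply(ev, nrow, 0L)
  expect_true(all(counts <= 2))
  frac <- mean(counts > 0)
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(frac - 1 / 3), 3 * se)
  for (e in ev[counts == 2]) {
    expect_gte(diff(sort(e$onset)), 0.8 - 1e-9)
  }
  for (e in ev[counts > 0]) {
    expect_true(all(e$onset >= 0 & e$onset + e$duration <= 3.5))
  }
  expect_true(all(vapply(placeEvents(50, pEventTrial = 0, seed = 1),
                         nrow, 0L) == 0L))
  expect_error(placeEvents(10, duration = 0.2), "duration")
  expect_error(placeEvents(10, duration = 1.0, minGap = 0.8), "gap")
})

test_that("stimulus validator flags injected violations", {
  trial <- generateTrial(stimulusBand("theta"), seed = 21)
  expect_identical(nrow(validateStimulus(trial)), 0L)
  ## out-of-band frequency in a theta trial
  bad <- trial
  bad@fmLeft@freq[100] <- 7.5
  v <- validateStimulus(bad)
  expect_true("band_containment" %in% v$constraint)
  expect_true("rate_limit" %in% v$constraint)  # 0.5 Hz jump in one frame
  ## injected correlated pair
  bad2 <- trial
  bad2@fmRight@freq <- bad2@fmLeft@freq + rnorm(350, 0, 0.01)
  v2 <- validateStimulus(bad2)
  expect_true("decorrelation" %in% v2$constraint)
  ## event-gap violation
  bad3 <- trial
  bad3@events <- data.frame(kind = c("target", "target"),
                            onset = c(1.0, 1.5), duration = 0.3)
  expect_true("event_gap" %in% validateStimulus(bad3)$constraint)
})

test_that("CMF spectral mass concentrates in the stimulation band", {
  ## long contrast modulation; compare demeaned spectral mass inside the
  ## band (plus half the grid step) against the total
  for (bandName in c("theta", "alpha", "beta")) {
    band <- stimulusBand(bandName)
    fm <- generateFMFunction(band, duration = 60, seed = 3)
    cmf <- fmToCMF(fm)
    x <- cmf@luminance - mean(cmf@luminance)
    n <- length(x)
    pw <- abs(fft(x))^2
    freqs <- (seq_len(n) - 1) * 100 / n
    half <- freqs <= 50
    inBand <- half & freqs >= band@fLo - 0.5 & freqs <= band@fHi + 0.5
    expect_gte(sum(pw[inBand]) / sum(pw[half]), 0.9)
  }
})

test_that("trial CSV export is tidy and complete", {
  trial <- generateTrial(stimulusBand("alpha"), seed = 2)
  path <- tempfile(fileext = ".csv")
  writeTrialsCSV(list(trial), path)
  df <- read.csv(path)
  expect_named(df, c("trial", "side", "frame", "time_s", "freq_hz",
                     "luminance_cdm2"))
  expect_equal(nrow(df), 2 * 350)
  unlink(path)
})
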