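test_that("during-stimulation epoching yields 5 epochs per clean trial", {
  m <- testMontage(16)
  sides <- rep(c("left", "right"), 2)
  trials <- lapply(1:4, function(k)
    generateTrial(stimulusBand("alpha"), attendedSide = sides[k],
                  seed = k))
  ## give one trial an event to test the exclusion flag
  trials[[2]]@events <- data.frame(kind = "target", onset = 1,
                                   duration = 0.3)
  sp <- subjectParams(iafTrue = 10, alphaAmp = 3)
  rec <- simulateRecording(sp, trials, m, seed = 2)
  epAll <- epochData(rec, excludeEventTrials = FALSE)
  expect_equal(dim(epAll@data)[1], 4 * 5)
  expect_equal(dim(epAll@data)[3], 512)
  epClean <- epochData(rec, excludeEventTrials = TRUE)
  expect_equal(dim(epClean@data)[1], 3 * 5)
  expect_false(any(epClean@info$hasEvent))
})

test_that("SCD operator is a zero-sum linear smoother", {
  m <- testMontage(16)
  x <- sin(2 * pi * 10 * (0:511) / 512)
  ep <- signalEpochs(x, nEpochs = 2, montage = m)
  ## spatially constant potential has (numerically) zero Laplacian
  scd <- scalpCurrentDensity(ep)
  expect_lt(max(abs(scd@data)), 1e-6 * max(abs(ep@data)))
  ## linearity of the operator
  A <- scdOperator(m)
  v1 <- rnorm(16)
  v2 <- rnorm(16)
  expect_equal(A %*% (2 * v1 - 3 * v2),
               2 * A %*% v1 - 3 * A %*% v2, tolerance = 1e-12)
  ## stronger regularization shrinks the output
  A2 <- scdOperator(m, lambda = 1e-1)
  v <- rnorm(16)
  expect_lt(sum((A2 %*% v)^2), sum((A %*% v)^2))
})

test_that("SCD of a focal source peaks at the source electrode", {
  m <- testMontage(16)
  pos <- channelPositions(m)
  src <- match(leftCluster(m)[1], channelLabels(m))
  ## potential spreading from one electrode with smooth spatial falloff
  d <- acos(pmin(1, pmax(-1, pos %*% pos[src, ])))
  v <- exp(-d^2 / (2 * 0.4^2))
  scd <- as.vector(scdOperator(m) %*% v)
  expect_equal(which.max(scd), src)
})

test_that("power spectra land on an exact 0.5 Hz grid with correct peaks
           and scaling", {
  m <- testMontage(16)
  fs <- 512
  t <- (0:(fs - 1)) / fs
  ep <- signalEpochs(sin(2 * pi * 10 * t), montage = m)
  ps <- powerSpectrum(ep)
  expect_equal(unique(round(diff(ps@freqs), 10)), 0.5)
  expect_equal(ps@freqs[which.max(ps@values[1, ])], 10)
  ## dB conversion and round trip
  expect_equal(toLogPower(syntheticSpectrum())@scale, "dB")
  p100 <- new("PowerSpectrum", freqs = c(1, 1.5), scale = "raw",
              values = matrix(100, 1, 2), channels = "ch01")
  expect_equal(toLogPower(p100)@values[1, 1], 20)
  rt <- toRawPower(toLogPower(syntheticSpectrum(noiseSd = 0.3)))
  expect_equal(rt@values, syntheticSpectrum(noiseSd = 0.3)@values,
               tolerance = 1e-12)
})

test_that("white-noise spectra are flat and conserve variance", {
  m <- testMontage(16)
  nEp <- 40
  arr <- withSeed(99, array(rnorm(nEp * 16 * 512), dim = c(nEp, 16, 512)))
  ep <- new("EpochSet", data = arr, fs = 512, montage = m,
            info = data.frame(trial = seq_len(nEp), offset = 0,
                              condition = "x", attendedSide = "left",
                              hasEvent = FALSE),
            scale = "potential")
  ps <- powerSpectrum(ep, fMax = Inf)
  tot <- rowSums(ps@values) * 0.5
  ## total power close to the unit variance of the input noise
  expect_equal(mean(tot), 1, tolerance = 0.12)
  ## flat within Monte-Carlo tolerance: compare lower and upper halves
  nF <- length(ps@freqs)
  lower <- mean(ps@values[, 2:(nF %/% 2)])
  upper <- mean(ps@values[, (nF %/% 2 + 1):nF])
  expect_equal(lower / upper, 1, tolerance = 0.1)
})

test_that("malformed montages are refused", {
  m <- testMontage(16)
  ## duplicate electrode positions break the spline system
  m2 <- m
  m2@positions[2, ] <- m2@positions[1, ]
  expect_error(scdOperator(m2), "duplicate")
})

test_that("spectrum pooling and channel averaging behave linearly", {
  a <- syntheticSpectrum(peakHz = 9, seed = 1)
  b <- syntheticSpectrum(peakHz = 11, seed = 2)
  pool <- poolSpectra(list(a, b))
  expect_equal(pool@values, (a@values + b@values) / 2)
  expect_equal(channelAverage(a), colMeans(a@values))
  expect_error(channelAverage(a, "nope"), "unknown channel")
})
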