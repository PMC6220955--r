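# Shared fixtures: montages are deterministic, so build them once.

fix <- new.env()

testMontage <- function(n = 16) {
  key <- paste0("m", n)
  if (is.null(fix[[key]])) fix[[key]] <- makeMontage(n)
  fix[[key]]
}

bothClusters <- function(m) c(leftCluster(m), rightCluster(m))

# Raw power spectrum on the 0.5 Hz grid: 1/f background plus an optional
# Gaussian alpha peak, with multiplicative noise. Mirrors the shape of the
# spectra the pipeline produces, without simulating EEG.
syntheticSpectrum <- function(peakHz = 10, peakAmp = 6, peakSd = 1,
                              noiseSd = 0, fMax = 40, nCh = 2, seed = 1,
                              background = TRUE) {
  freqs <- seq(0.5, fMax, by = 0.5)
  base <- if (background) 5 / freqs else rep(1, length(freqs))
  shape <- base + peakAmp * exp(-(freqs - peakHz)^2 / (2 * peakSd^2))
  m <- testMontage(16)
  vals <- withSeed(seed, {
    t(vapply(seq_len(nCh), function(i)
      shape * exp(rnorm(length(freqs), 0, noiseSd)), freqs))
  })
  new("PowerSpectrum", freqs = freqs, values = vals, scale = "raw",
      channels = channelLabels(m)[seq_len(nCh)])
}

withSeed <- alphakit:::withSeed

# epoch set holding identical copies of one channel-uniform signal
signalEpochs <- function(x, nEpochs = 3, montage = testMontage(16),
                         fs = 512) {
  nCh <- length(channelLabels(montage))
  arr <- array(rep(x, each = nEpochs * nCh),
               dim = c(nEpochs, nCh, length(x)))
  new("EpochSet", data = arr, fs = fs, montage = montage,
      info = data.frame(trial = seq_len(nEpochs), offset = 0,
                        condition = "x", attendedSide = "left",
                        hasEvent = FALSE),
      scale = "potential")
}
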