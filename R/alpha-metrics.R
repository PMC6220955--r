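## Alpha observables: individual alpha frequency (IAF) via the
## sign-flipped second-gradient + Savitzky-Golay method, individual alpha
## power (IAP), lateralization index, and a phase-locking-value utility.

#' Detect the individual alpha frequency of a spectrum
#'
#' The raw spectrum is averaged over the requested channels, its second
#' numerical gradient is taken and sign-flipped (so spectral peaks, i.e.
#' points of locally maximal negative curvature, become positive maxima,
#' which accentuates indistinct peaks riding on the 1/f background), and
#' the result is smoothed with an 11-point third-order Savitzky-Golay
#' filter applied without padding (edge samples are excluded from the
#' search). The IAF is the grid frequency of the highest positive interior
#' local maximum within the search window; ties break toward the lower
#' frequency.
#'
#' @param ps a raw-scale [PowerSpectrum-class] covering at least
#'   `searchLo - 3` to `searchHi + 3` Hz
#' @param channels channel labels to average over (default: all)
#' @param searchLo,searchHi IAF search window in Hz (defaults 6 and 14)
#' @param sgLength,sgOrder Savitzky-Golay window length and polynomial
#'   order (defaults 11 and 3)
#' @return IAF in Hz on the spectrum's grid, or `NA` (with attribute
#'   `reason = "no peak"`) when no positive interior maximum exists
#' @export
detectIAF <- function(ps, channels = NULL, searchLo = 6, searchHi = 14,
                      sgLength = 11, sgOrder = 3) {
  if (ps@scale != "raw") stop("detectIAF operates on raw power spectra")
  df <- ps@freqs[2] - ps@freqs[1]
  if (min(ps@freqs) > searchLo - 3 || max(ps@freqs) < searchHi + 3)
    stop("spectrum must cover the search window plus 3 Hz margins")
  p <- channelAverage(ps, channels)
  if (length(p) < sgLength)
    stop("need at least ", sgLength, " grid points for the SG filter")
  s <- -numGradient(numGradient(p, df), df)
  ## central Savitzky-Golay smoothing row; edges left as NA (no padding)
  coefs <- signal::sgolay(p = sgOrder, n = sgLength)
  mid <- (sgLength + 1L) %/% 2L
  sm <- stats::filter(s, coefs[mid, ], method = "convolution", sides = 2)
  sm <- as.numeric(sm)
  n <- length(sm)
  inWin <- ps@freqs >= searchLo & ps@freqs <= searchHi
  isMax <- rep(FALSE, n)
  idx <- 2:(n - 1)
  isMax[idx] <- !is.na(sm[idx]) & !is.na(sm[idx - 1]) & !is.na(sm[idx + 1]) &
    sm[idx] > sm[idx - 1] & sm[idx] >= sm[idx + 1] & sm[idx] > 0
  cand <- which(isMax & inWin)
  if (length(cand) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "no peak"
    return(out)
  }
  top <- max(sm[cand])
  best <- cand[sm[cand] >= top - 1e-9 * max(abs(top), 1)]
  ps@freqs[min(best)]
}

#' Individual alpha power around the IAF
#'
#' Mean log-power over the grid points within `iaf` plus/minus
#' `halfwidth` Hz (5 points on the 0.5 Hz grid), averaged across the
#' requested channels.
#'
#' @param psDb a dB-scale [PowerSpectrum-class]
#' @param iaf individual alpha frequency in Hz
#' @param channels channel labels to average over (default: all)
#' @param halfwidth band half-width in Hz (default 1)
#' @return IAP in dB
#' @export
computeIAP <- function(psDb, iaf, channels = NULL, halfwidth = 1) {
  if (psDb@scale != "dB") stop("computeIAP operates on log-power spectra")
  if (is.na(iaf)) return(NA_real_)
  lo <- iaf - halfwidth
  hi <- iaf + halfwidth
  if (lo < min(psDb@freqs) - 1e-9 || hi > max(psDb@freqs) + 1e-9)
    stop("IAF band extends beyond the spectrum")
  p <- channelAverage(psDb, channels)
  sel <- psDb@freqs >= lo - 1e-9 & psDb@freqs <= hi + 1e-9
  mean(p[sel])
}

#' Alpha lateralization index
#'
#' IAP over the cluster contralateral to the attended position minus IAP
#' over the ipsilateral cluster; negative under contralateral suppression.
#'
#' @param iapContra,iapIpsi cluster IAP values in dB
#' @return lateralization in dB
#' @export
lateralizationIndex <- function(iapContra, iapIpsi) {
  if (anyNA(c(iapContra, iapIpsi))) stop("missing cluster IAP")
  iapContra - iapIpsi
}

## analytic signal via FFT (Hilbert transform)
analyticSignal <- function(x) {
  n <- length(x)
  z <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(z * h, inverse = TRUE) / n
}

#' Phase-locking value between EEG epochs and a stimulus phase
#'
#' Band-passes each EEG epoch, extracts its instantaneous phase from the
#' analytic signal, and computes the magnitude of the across-epoch mean
#' unit phasor of the EEG-stimulus phase difference, averaged over time.
#'
#' @param eeg epochs x samples matrix (or a vector for a single epoch)
#' @param stimPhase epochs x samples matrix of unwrapped stimulus phase
#'   (or a vector recycled across epochs)
#' @param band length-2 numeric band in Hz
#' @param fs sampling rate in Hz
#' @param order Butterworth filter order (default 4)
#' @return PLV in [0, 1]
#' @export
phaseLockingValue <- function(eeg, stimPhase, band, fs, order = 4) {
  if (is.vector(eeg)) eeg <- matrix(eeg, nrow = 1)
  if (is.vector(stimPhase))
    stimPhase <- matrix(stimPhase, nrow = nrow(eeg), ncol = length(stimPhase),
                        byrow = TRUE)
  stopifnot(all(dim(eeg) == dim(stimPhase)))
  if (band[1] >= band[2]) stop("degenerate frequency band")
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  nE <- nrow(eeg)
  ph <- matrix(0, nE, ncol(eeg))
  for (i in seq_len(nE)) {
    xf <- signal::filtfilt(bf, eeg[i, ])
    ph[i, ] <- Arg(analyticSignal(xf))
  }
  dphi <- ph - stimPhase
  phasor <- exp(1i * dphi)
  mean(abs(colMeans(phasor)))
}

#' Assemble an alpha-profile table row
#'
#' @param subject subject identifier
#' @param condition condition label
#' @param iaf IAF in Hz
#' @param iap IAP in dB
#' @param lateralization lateralization index in dB (optional)
#' @return one-row data.frame (subject, condition, iaf, iap,
#'   lateralization)
#' @export
alphaProfile <- function(subject, condition, iaf, iap,
                         lateralization = NA_real_) {
  data.frame(subject = subject, condition = condition, iaf = iaf,
             iap = iap, lateralization = lateralization)
}
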