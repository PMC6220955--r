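## Epoching and spectral decomposition: 1-s epochs with 0.5-s overlap,
## spherical-spline scalp current densities, detrended Hann-tapered
## zero-padded FFT power on a 0.5 Hz grid, decibel conversion.

#' Cut a recording into 1-s epochs with 0.5-s overlap
#'
#' For during-stimulation recordings, a 3-s window starting 0.5 s after
#' each stimulation onset is cut into 1-s epochs with 0.5-s overlap (5
#' epochs per trial); the initial 0.5 s avoid onset-evoked activity and
#' the final 0.5 s the offset. Peri recordings are segmented whole.
#'
#' @param rec a [Recording-class]
#' @param kind "during" or "peri"; defaults to the recording's own kind
#' @param excludeEventTrials drop trials containing targets/distracters
#'   (default TRUE, only relevant for during-recordings)
#' @return an [EpochSet-class]
#' @export
epochData <- function(rec, kind = rec@segmentKind,
                      excludeEventTrials = TRUE) {
  fs <- round(rec@fs)
  step <- fs %/% 2L
  epochs <- list()
  info <- list()
  if (kind == "during") {
    stimSamp <- if (length(rec@trials))
      round(length(rec@trials[[1]]@fmLeft@t) /
            rec@trials[[1]]@fmLeft@frameRate * fs) else 0L
    for (k in seq_along(rec@trials)) {
      tr <- rec@trials[[k]]
      hasEvent <- nrow(tr@events) > 0L
      if (excludeEventTrials && hasEvent) next
      start <- rec@onsets[k] + step  # 0.5 s after onset
      winLen <- stimSamp - step      # 3 s of a 3.5-s stimulation
      if (winLen < fs) {
        message("trial ", k, " shorter than the analysis window; skipped")
        next
      }
      offsets <- seq(0L, winLen - fs, by = step)
      for (o in offsets) {
        epochs[[length(epochs) + 1L]] <-
          rec@data[, (start + o):(start + o + fs - 1L), drop = FALSE]
        info[[length(info) + 1L]] <- data.frame(
          trial = k, offset = o / fs, condition = tr@condition,
          attendedSide = tr@attendedSide, hasEvent = hasEvent)
      }
    }
  } else {
    n <- ncol(rec@data)
    starts <- seq(1L, n - fs + 1L, by = step)
    for (s in starts) {
      epochs[[length(epochs) + 1L]] <-
        rec@data[, s:(s + fs - 1L), drop = FALSE]
      info[[length(info) + 1L]] <- data.frame(
        trial = NA_integer_, offset = (s - 1L) / fs, condition = "peri",
        attendedSide = NA_character_, hasEvent = FALSE)
    }
  }
  if (length(epochs) == 0L) stop("no epochs could be extracted")
  arr <- array(0, dim = c(length(epochs), nrow(rec@data), fs))
  for (i in seq_along(epochs)) arr[i, , ] <- epochs[[i]]
  new("EpochSet", data = arr, fs = rec@fs, montage = rec@montage,
      info = do.call(rbind, info), scale = "potential")
}

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet (%s): %d epochs x %d channels x %d samples @ %g Hz\n",
              object@scale, d[1], d[2], d[3], object@fs))
})

## Legendre polynomials P_1..P_nmax evaluated at matrix x, as a list
legendreSeries <- function(x, nmax) {
  out <- vector("list", nmax)
  pPrev <- array(1, dim = dim(x))  # P_0
  p <- x                           # P_1
  out[[1]] <- p
  if (nmax > 1) for (nn in 2:nmax) {
    pNext <- ((2 * nn - 1) * x * p - (nn - 1) * pPrev) / nn
    out[[nn]] <- pNext
    pPrev <- p
    p <- pNext
  }
  out
}

#' Spherical-spline scalp-current-density operator
#'
#' Builds the linear operator mapping scalp potentials to the
#' surface-Laplacian (scalp current density) estimate by the spherical
#' spline method with regularization `lambda` added to the diagonal of the
#' spline kernel and the spline coefficients constrained to sum to zero.
#'
#' @param montage a [Montage-class]
#' @param m spline order (default 4)
#' @param lambda regularization (default 1e-4)
#' @param nLegendre number of Legendre terms (default 20)
#' @return nChannels x nChannels matrix; SCD = operator %*% potentials
#' @export
scdOperator <- function(montage, m = 4, lambda = 1e-4, nLegendre = 20) {
  pos <- montage@positions
  nCh <- nrow(pos)
  cosang <- pos %*% t(pos)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10))
    stop("duplicate electrode positions in montage")
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  P <- legendreSeries(cosang, nLegendre)
  G <- matrix(0, nCh, nCh)
  H <- matrix(0, nCh, nCh)
  for (nn in seq_len(nLegendre)) {
    G <- G + (2 * nn + 1) / (nn * (nn + 1))^m * P[[nn]]
    H <- H + (2 * nn + 1) / (nn * (nn + 1))^(m - 1) * P[[nn]]
  }
  G <- G / (4 * pi)
  H <- H / (4 * pi)
  ## augmented system enforcing sum(c) = 0
  A <- rbind(cbind(G + diag(lambda, nCh), rep(1, nCh)),
             c(rep(1, nCh), 0))
  Ainv <- solve(A)
  H %*% Ainv[seq_len(nCh), seq_len(nCh)]
}

#' Convert epochs to scalp current densities
#'
#' Applies the spherical-spline surface-Laplacian operator (see
#' [scdOperator()]) to every epoch, yielding a reference-free estimate of
#' radial current flow.
#'
#' @param epochs an [EpochSet-class] on the potential scale
#' @param m,lambda,nLegendre passed to [scdOperator()]
#' @return an [EpochSet-class] with `scale = "scd"`
#' @export
scalpCurrentDensity <- function(epochs, m = 4, lambda = 1e-4,
                                nLegendre = 20) {
  if (dim(epochs@data)[2] < 8) stop("at least 8 channels required for SCD")
  A <- scdOperator(epochs@montage, m, lambda, nLegendre)
  d <- dim(epochs@data)
  out <- epochs@data
  for (i in seq_len(d[1])) out[i, , ] <- A %*% epochs@data[i, , ]
  new("EpochSet", data = out, fs = epochs@fs, montage = epochs@montage,
      info = epochs@info, scale = "scd")
}

#' Average power spectrum of an epoch set
#'
#' Per epoch and channel: mean and linear trend are removed, the series is
#' Hann-tapered, zero-padded to `ceil(2 * fs)` samples (0.5 Hz resolution)
#' and Fourier-transformed; squared magnitudes are normalized as a
#' one-sided spectral density and averaged across epochs.
#'
#' @param epochs an [EpochSet-class] (1-s epochs)
#' @param resolutionHz target frequency resolution (default 0.5)
#' @param fMax truncate the grid at this frequency (default 40 Hz;
#'   use `Inf` for the full grid up to Nyquist)
#' @return a raw-scale [PowerSpectrum-class]
#' @export
powerSpectrum <- function(epochs, resolutionHz = 0.5, fMax = 40) {
  d <- dim(epochs@data)
  if (d[1] == 0L) stop("empty epoch set")
  nS <- d[3]
  fs <- epochs@fs
  padTo <- ceiling(fs / resolutionHz)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nS) / (nS + 1)))  # Hann taper
  ## detrend basis projection (mean + linear trend)
  B <- cbind(1, seq_len(nS))
  Pb <- B %*% solve(crossprod(B), t(B))
  ## flatten epochs x channels into columns
  X <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = nS)
  X <- X - Pb %*% X
  X <- X * w
  Xp <- rbind(X, matrix(0, padTo - nS, ncol(X)))
  Z <- mvfft(Xp)
  nF <- padTo %/% 2L + 1L
  pw <- abs(Z[seq_len(nF), , drop = FALSE])^2
  scale <- 2 / (fs * sum(w^2))
  pw <- pw * scale
  pw[1, ] <- pw[1, ] / 2
  pw[nF, ] <- pw[nF, ] / 2
  ## average across epochs per channel
  avg <- rowMeans(array(pw, dim = c(nF, d[2], d[1])), dims = 2)
  freqs <- (seq_len(nF) - 1L) * fs / padTo
  keep <- freqs <= fMax
  new("PowerSpectrum", freqs = freqs[keep],
      values = t(avg[keep, , drop = FALSE]), scale = "raw",
      channels = epochs@montage@labels)
}

#' Convert a power spectrum to decibel log-power
#'
#' @param ps a raw-scale [PowerSpectrum-class]
#' @return the same spectrum with values `10 * log10(power)`
#' @export
toLogPower <- function(ps) {
  if (ps@scale == "dB") return(ps)
  new("PowerSpectrum", freqs = ps@freqs, values = 10 * log10(ps@values),
      scale = "dB", channels = ps@channels)
}

#' @describeIn toLogPower inverse conversion back to raw power
#' @export
toRawPower <- function(ps) {
  if (ps@scale == "raw") return(ps)
  new("PowerSpectrum", freqs = ps@freqs, values = 10^(ps@values / 10),
      scale = "raw", channels = ps@channels)
}

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf(
    "PowerSpectrum (%s): %d channels, %g-%g Hz (step %g Hz)\n",
    object@scale, nrow(object@values), min(object@freqs), max(object@freqs),
    object@freqs[2] - object@freqs[1]))
})

#' Average spectrum over a channel subset
#'
#' @param ps a [PowerSpectrum-class]
#' @param channels labels to average over (default: all)
#' @return numeric vector over the frequency grid
#' @export
channelAverage <- function(ps, channels = NULL) {
  if (is.null(channels)) channels <- ps@channels
  idx <- match(channels, ps@channels)
  if (anyNA(idx)) stop("unknown channel label(s)")
  colMeans(ps@values[idx, , drop = FALSE])
}

#' Pool several spectra (e.g. across conditions) by averaging
#'
#' Spectra must share scale, grid and channels. Raw spectra are averaged
#' on the raw scale; dB spectra on the dB scale.
#'
#' @param psList list of [PowerSpectrum-class]
#' @return a [PowerSpectrum-class]
#' @export
poolSpectra <- function(psList) {
  stopifnot(length(psList) >= 1L)
  v <- Reduce(`+`, lapply(psList, slot, "values")) / length(psList)
  p1 <- psList[[1]]
  new("PowerSpectrum", freqs = p1@freqs, values = v, scale = p1@scale,
      channels = p1@channels)
}
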