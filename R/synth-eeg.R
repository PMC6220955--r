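## Synthetic multi-channel EEG: 1/f background, per-hemisphere alpha
## oscillators with attention gains, optional stimulus-locked
## frequency-following response and Adler-type phase entrainment.

#' Construct subject-level generator parameters
#'
#' @param iafTrue intrinsic alpha peak frequency in Hz (6-14)
#' @param alphaAmp alpha oscillator amplitude (a.u.)
#' @param attnModulation attention gain per hemisphere in dB of power: the
#'   cluster contralateral to the attended position is attenuated by this
#'   amount, the ipsilateral cluster symmetrically enhanced
#' @param noiseExponent spectral slope of the 1/f background (default 1)
#' @param noiseAmp background noise amplitude (a.u.)
#' @param driveSnr amplitude of the stimulus-locked frequency-following
#'   component (0 disables it)
#' @param entrainCoupling Adler coupling strength epsilon in rad/s
#'   (0 disables entrainment)
#' @param behaviorIntercept,behaviorSlope logit-linear accuracy model
#'   parameters
#' @return a [SubjectParams-class]
#' @export
subjectParams <- function(iafTrue = 10, alphaAmp = 4, attnModulation = 2,
                          noiseExponent = 1, noiseAmp = 1, driveSnr = 0,
                          entrainCoupling = 0, behaviorIntercept = 1.2,
                          behaviorSlope = 0) {
  new("SubjectParams", iafTrue = iafTrue, alphaAmp = alphaAmp,
      attnModulation = attnModulation, noiseExponent = noiseExponent,
      noiseAmp = noiseAmp, driveSnr = driveSnr,
      entrainCoupling = entrainCoupling,
      behaviorIntercept = behaviorIntercept, behaviorSlope = behaviorSlope)
}

setMethod("show", "SubjectParams", function(object) {
  cat(sprintf(
    "SubjectParams: IAF %.2f Hz, alphaAmp %.2f, attn %.1f dB, eps %.2f rad/s\n",
    object@iafTrue, object@alphaAmp, object@attnModulation,
    object@entrainCoupling))
})

#' Draw a simulated cohort
#'
#' Subject IAFs are drawn from a truncated normal (mean 10.2 Hz, sd 0.9,
#' bounds 8-13 Hz); alpha amplitudes vary moderately across subjects.
#'
#' @param n cohort size (default 17)
#' @param seed integer RNG seed
#' @param iafMean,iafSd IAF population parameters
#' @param ... further arguments passed to [subjectParams()] and shared by
#'   all subjects (e.g. `attnModulation`, `entrainCoupling`)
#' @return list of [SubjectParams-class]
#' @export
makeCohort <- function(n = 17, seed = 1L, iafMean = 10.2, iafSd = 0.9, ...) {
  withSeed(seed, {
    iaf <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- rnorm(1, iafMean, iafSd)
        if (v >= 8 && v <= 13) break
      }
      iaf[i] <- v
    }
    amp <- pmax(1.5, rnorm(n, 4, 0.8))
    lapply(seq_len(n), function(i)
      subjectParams(iafTrue = iaf[i], alphaAmp = amp[i], ...))
  })
}

## 1/f noise by spectral shaping; columns are channels. The random
## spectrum is drawn directly with Hermitian symmetry so one inverse FFT
## suffices. Output columns have unit variance before scaling by `amp`.
oneOverFNoise <- function(n, nCol, fs, exponent = 1, amp = 1) {
  if (exponent == 0) return(amp * matrix(rnorm(n * nCol), n, nCol))
  half <- (n - 1) %/% 2                      # strictly positive freqs
  f <- seq_len(half) * fs / n
  sc <- f^(-exponent / 2)
  z <- matrix(0i, n, nCol)
  re <- matrix(rnorm(half * nCol), half, nCol) * sc
  im <- matrix(rnorm(half * nCol), half, nCol) * sc
  z[2:(half + 1), ] <- complex(real = re, imaginary = im)
  z[n:(n - half + 1), ] <- Conj(z[2:(half + 1), ])
  if (n %% 2 == 0)                           # real Nyquist bin
    z[n / 2 + 1, ] <- rnorm(nCol) * (fs / 2)^(-exponent / 2)
  x <- Re(mvfft(z, inverse = TRUE)) / sqrt(n)
  x <- sweep(x, 2, apply(x, 2, sd), "/")
  amp * x
}

## slow positive amplitude envelope (~1 Hz bandwidth fluctuations)
slowEnvelope <- function(n, fs, cutoff = 1, depth = 0.35) {
  z <- fft(rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  z[f > cutoff] <- 0
  x <- Re(fft(z, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x / s
  pmax(0.05, 1 + depth * x)
}

## Gaussian spatial gains from a source direction to all channels
sourceGains <- function(montage, direction, sigma = 0.6) {
  d <- angDist(montage@positions, direction / sqrt(sum(direction^2)))
  exp(-d^2 / (2 * sigma^2))
}

## unit direction of a channel cluster's centroid
clusterDirection <- function(montage, labels) {
  idx <- match(labels, montage@labels)
  v <- colMeans(montage@positions[idx, , drop = FALSE])
  v / sqrt(sum(v^2))
}

## resample an unwrapped CMF phase from the frame grid to the EEG grid
resamplePhase <- function(cmf, fs, nOut) {
  tOut <- (seq_len(nOut) - 1L) / fs
  approx(cmf@t, cmf@phase, xout = tOut, rule = 2)$y
}

## integrate the alpha oscillator phase over one stimulation window:
## dphi/dt = 2*pi*iaf + eps * sin(phiStim - phi)  (Adler equation)
adlerPhase <- function(phi0, iaf, eps, phiStim, fs) {
  n <- length(phiStim)
  dt <- 1 / fs
  phi <- numeric(n)
  p <- phi0
  base <- 2 * pi * iaf * dt
  for (k in seq_len(n)) {
    p <- p + base + eps * sin(phiStim[k] - p) * dt
    phi[k] <- p
  }
  phi
}

#' Simulate a multi-channel EEG recording during stimulation
#'
#' Each trial consists of a cue period, the stimulation window and an idle
#' period. The signal at every channel is a projection of two
#' parieto-occipital alpha sources (one per hemisphere, instantaneous
#' frequency `iafTrue`, slow amplitude envelope) plus 1/f background noise.
#' During a trial, the source contralateral to the attended position is
#' attenuated by `attnModulation` dB and the ipsilateral source enhanced
#' symmetrically. A frequency-following component with amplitude `driveSnr`
#' tracks the attended stimulus' contrast-modulation phase, and with
#' `entrainCoupling > 0` the alpha phase obeys the Adler equation during
#' stimulation.
#'
#' @param subject a [SubjectParams-class]
#' @param trials non-empty list of [TrialSpec-class]
#' @param montage a [Montage-class] with defined clusters
#' @param fs sampling rate in Hz (>= 256; default 512)
#' @param seed integer RNG seed
#' @param cueDur,idleDur cue and inter-trial durations in s
#' @return a [Recording-class] with `segmentKind = "during"`
#' @export
simulateRecording <- function(subject, trials, montage, fs = 512,
                              seed = 1L, cueDur = 0.5, idleDur = 0.7) {
  if (length(trials) == 0L) stop("trials must be non-empty")
  if (fs < 256) stop("fs must be >= 256 Hz")
  if (length(montage@leftCluster) == 0L ||
      length(montage@rightCluster) == 0L)
    stop("montage must define left and right clusters")
  stimDur <- length(trials[[1]]@fmLeft@t) / trials[[1]]@fmLeft@frameRate
  trialSamp <- round((cueDur + stimDur + idleDur) * fs)
  stimSamp <- round(stimDur * fs)
  cueSamp <- round(cueDur * fs)
  nTrials <- length(trials)
  n <- trialSamp * nTrials
  nCh <- length(montage@labels)
  onsets <- as.integer((seq_len(nTrials) - 1L) * trialSamp + cueSamp + 1L)

  withSeed(seed, {
    ## per-hemisphere oscillator phases (free-running baseline)
    dt <- 1 / fs
    phi0 <- runif(2, 0, 2 * pi)
    phiL <- phi0[1] + 2 * pi * subject@iafTrue * dt * seq_len(n)
    phiR <- phi0[2] + 2 * pi * subject@iafTrue * dt * seq_len(n)
    ## splice an entrained phase segment into a free-running trajectory,
    ## keeping the phase continuous at both window edges
    splice <- function(phi, win, phiStim) {
      prev <- if (win[1] > 1L) phi[win[1] - 1L] else phi[1] -
        2 * pi * subject@iafTrue * dt
      newP <- adlerPhase(prev, subject@iafTrue, subject@entrainCoupling,
                         phiStim, fs)
      last <- win[length(win)]
      offset <- newP[length(newP)] - phi[last]
      phi[win] <- newP
      if (last < n) phi[(last + 1L):n] <- phi[(last + 1L):n] + offset
      phi
    }
    drive <- numeric(n)
    for (k in seq_len(nTrials)) {
      win <- onsets[k]:(onsets[k] + stimSamp - 1L)
      cmf <- if (trials[[k]]@attendedSide == "left")
        trials[[k]]@cmfLeft else trials[[k]]@cmfRight
      phiStim <- resamplePhase(cmf, fs, stimSamp)
      if (subject@driveSnr > 0)
        drive[win] <- subject@driveSnr * sin(phiStim)
      if (subject@entrainCoupling > 0) {
        phiL <- splice(phiL, win, phiStim)
        phiR <- splice(phiR, win, phiStim)
      }
    }
    envL <- slowEnvelope(n, fs)
    envR <- slowEnvelope(n, fs)
    ## attention gain per hemisphere (amplitude scale, whole trial span)
    gainL <- rep(1, n)
    gainR <- rep(1, n)
    aUp <- 10^(subject@attnModulation / 20)
    aDn <- 10^(-subject@attnModulation / 20)
    for (k in seq_len(nTrials)) {
      span <- ((k - 1L) * trialSamp + 1L):(k * trialSamp)
      if (trials[[k]]@attendedSide == "left") {
        gainL[span] <- aUp   # ipsilateral to attended position
        gainR[span] <- aDn   # contralateral: suppressed
      } else {
        gainL[span] <- aDn
        gainR[span] <- aUp
      }
    }
    srcL <- subject@alphaAmp * gainL * envL * sin(phiL) + drive
    srcR <- subject@alphaAmp * gainR * envR * sin(phiR) + drive

    gL <- sourceGains(montage, clusterDirection(montage, montage@leftCluster))
    gR <- sourceGains(montage, clusterDirection(montage, montage@rightCluster))
    sig <- outer(gL, srcL) + outer(gR, srcR)
    noise <- t(oneOverFNoise(n, nCh, fs, subject@noiseExponent,
                             subject@noiseAmp))
    common <- oneOverFNoise(n, 1L, fs, subject@noiseExponent,
                            0.3 * subject@noiseAmp)[, 1]
    dataMat <- sig + noise + matrix(common, nCh, n, byrow = TRUE)
    rownames(dataMat) <- montage@labels
    new("Recording", data = dataMat, fs = fs, montage = montage,
        trials = trials, onsets = onsets, subject = subject,
        segmentKind = "during")
  })
}

#' Simulate a peri-stimulation (resting) recording
#'
#' Same generative model as [simulateRecording()] with the
#' frequency-following drive, entrainment coupling and attention
#' modulation all switched off; emulates the concatenated resting segments
#' recorded immediately before and after stimulation blocks.
#'
#' @param subject a [SubjectParams-class]
#' @param duration total duration in s (>= 6; default 96, i.e. 16 segments
#'   of 6 s)
#' @param montage a [Montage-class]
#' @param fs sampling rate in Hz (default 512)
#' @param seed integer RNG seed
#' @return a [Recording-class] with `segmentKind = "peri"`
#' @export
simulatePeri <- function(subject, duration = 96, montage, fs = 512,
                         seed = 1L) {
  if (duration < 6) stop("duration must be >= 6 s")
  n <- round(duration * fs)
  nCh <- length(montage@labels)
  withSeed(seed, {
    dt <- 1 / fs
    phi0 <- runif(2, 0, 2 * pi)
    phiL <- phi0[1] + 2 * pi * subject@iafTrue * dt * seq_len(n)
    phiR <- phi0[2] + 2 * pi * subject@iafTrue * dt * seq_len(n)
    srcL <- subject@alphaAmp * slowEnvelope(n, fs) * sin(phiL)
    srcR <- subject@alphaAmp * slowEnvelope(n, fs) * sin(phiR)
    gL <- sourceGains(montage, clusterDirection(montage, montage@leftCluster))
    gR <- sourceGains(montage, clusterDirection(montage, montage@rightCluster))
    sig <- outer(gL, srcL) + outer(gR, srcR)
    noise <- t(oneOverFNoise(n, nCh, fs, subject@noiseExponent,
                             subject@noiseAmp))
    common <- oneOverFNoise(n, 1L, fs, subject@noiseExponent,
                            0.3 * subject@noiseAmp)[, 1]
    dataMat <- sig + noise + matrix(common, nCh, n, byrow = TRUE)
    rownames(dataMat) <- montage@labels
    new("Recording", data = dataMat, fs = fs, montage = montage,
        trials = list(), onsets = integer(0), subject = subject,
        segmentKind = "peri")
  })
}

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording (%s): %d channels x %d samples @ %g Hz, %d trial(s)\n",
    object@segmentKind, nrow(object@data), ncol(object@data), object@fs,
    length(object@trials)))
})

#' Simulate behavioural accuracies from standardized alpha power
#'
#' Accuracy follows a logit-linear model in standardized individual alpha
#' power: `logit(acc) = intercept + slope * iapZ + noise`.
#'
#' @param subjects list of [SubjectParams-class] (supplies intercepts and
#'   slopes), or `NULL` to use `intercept`/`slope` directly
#' @param iapZ standardized alpha power, one value per subject
#' @param seed integer RNG seed
#' @param noiseSd logit-scale noise standard deviation (default 0.3)
#' @param intercept,slope scalar model parameters used when
#'   `subjects = NULL`
#' @return numeric vector of accuracies in (0, 1)
#' @export
simulateBehavior <- function(subjects = NULL, iapZ, seed = 1L,
                             noiseSd = 0.3, intercept = 1.2, slope = 0) {
  stopifnot(all(is.finite(iapZ)))
  if (!is.null(subjects)) {
    intercept <- vapply(subjects, function(s) s@behaviorIntercept, 0)
    slope <- vapply(subjects, function(s) s@behaviorSlope, 0)
  }
  withSeed(seed, {
    lin <- intercept + slope * iapZ + rnorm(length(iapZ), 0, noiseSd)
    plogis(lin)
  })
}

#' Smooth random null topographies
#'
#' Draws per-subject sensor topographies as spatially smoothed Gaussian
#' noise on the montage. Two independent draws per subject form an
#' exchangeable pair with no systematic condition difference, the null
#' regime for calibrating the cluster-based permutation test.
#'
#' @param nSubjects number of subjects
#' @param montage a [Montage-class]
#' @param seed integer RNG seed
#' @param sigma spatial smoothing scale in radians (default 0.5)
#' @return nSubjects x nChannels matrix
#' @export
nullTopographies <- function(nSubjects, montage, seed = 1L, sigma = 0.5) {
  pos <- montage@positions
  gram <- pos %*% t(pos)
  gram[gram > 1] <- 1
  gram[gram < -1] <- -1
  d <- acos(gram)
  K <- exp(-d^2 / (2 * sigma^2))
  ev <- eigen(K, symmetric = TRUE)
  Khalf <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(0, ev$values)))
  withSeed(seed, {
    w <- matrix(rnorm(nSubjects * nrow(pos)), nSubjects, nrow(pos))
    w %*% t(Khalf)
  })
}
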