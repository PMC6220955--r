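## Quasi-periodic stimulus synthesis: FM functions, contrast-modulation
## functions, decorrelated pairs and target/distracter event placement.

#' Construct a stimulus band
#'
#' @param name one of "theta", "alpha", "beta" for the presets
#'   (4-7, 8-13, 14-20 Hz), or any label when `fLo`/`fHi` are given.
#' @param fLo,fHi band edges in Hz (optional for the presets)
#' @return a [StimulusBand-class]
#' @examples
#' stimulusBand("theta")
#' stimulusBand("custom", 9, 11)
#' @export
stimulusBand <- function(name, fLo = NULL, fHi = NULL) {
  presets <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 20))
  if (is.null(fLo) || is.null(fHi)) {
    if (!name %in% names(presets))
      stop("unknown band preset '", name, "'; give fLo and fHi")
    fLo <- presets[[name]][1]
    fHi <- presets[[name]][2]
  }
  new("StimulusBand", name = name, fLo = fLo, fHi = fHi)
}

#' @describeIn stimulusBand bandwidth in Hz (fHi - fLo)
#' @param band a [StimulusBand-class]
#' @export
bandwidth <- function(band) band@fHi - band@fLo

#' @describeIn stimulusBand band centre frequency in Hz
#' @export
bandCentre <- function(band) (band@fLo + band@fHi) / 2

setMethod("show", "StimulusBand", function(object) {
  cat(sprintf("StimulusBand '%s': %g-%g Hz (bandwidth %g Hz)\n",
              object@name, object@fLo, object@fHi, bandwidth(object)))
})

#' Generate a quasi-periodic frequency-modulation function
#'
#' Draws an instantaneous-frequency trajectory that wanders randomly inside
#' the stimulation band. Uniform random knots placed at 1-s spacing are
#' interpolated to the frame grid with a shape-preserving monotone cubic
#' (Fritsch-Carlson), then a forward clamp enforces the rate-of-change
#' limit of one bandwidth per second together with band containment.
#'
#' @param band a [StimulusBand-class]
#' @param duration stimulation duration in seconds (default 3.5)
#' @param frameRate display refresh rate in frames/s (default 100)
#' @param seed integer RNG seed; identical seeds give identical trajectories
#' @return an [FMFunction-class] of `duration * frameRate` frames
#' @examples
#' fm <- generateFMFunction(stimulusBand("theta"), seed = 1)
#' range(fmFrequencies(fm))
#' @export
generateFMFunction <- function(band, duration = 3.5, frameRate = 100,
                               seed = 1L) {
  f <- .fmTrajectory(band, duration, frameRate, seed)
  n <- length(f)
  new("FMFunction", t = (seq_len(n) - 1L) / frameRate, freq = f,
      band = band, frameRate = frameRate, seed = as.integer(seed))
}

## trajectory numerics without the S4 wrapper (hot path: the
## decorrelation rejection loop evaluates many candidates)
.fmTrajectory <- function(band, duration, frameRate, seed) {
  if (duration <= 0) stop("duration must be positive")
  if (frameRate <= 0) stop("frameRate must be positive")
  n <- round(duration * frameRate)
  tt <- (seq_len(n) - 1L) / frameRate
  bw <- bandwidth(band)
  if (bw == 0) {
    f <- rep(band@fLo, n)
  } else {
    f <- withSeed(seed, {
      knotT <- seq(0, ceiling(duration) + 1, by = 1)
      knotF <- runif(length(knotT), band@fLo, band@fHi)
      .monoCubic(knotT, knotF, tt)
    })
    ## forward clamp: joint projection onto the band and the
    ## |df/dt| <= bandwidth constraint (both preserved inductively);
    ## the interpolant rarely violates either, so the scalar pass only
    ## runs when needed
    maxStep <- bw / frameRate
    fLo <- band@fLo; fHi <- band@fHi
    f[f < fLo] <- fLo
    f[f > fHi] <- fHi
    if (any(abs(diff(f)) > maxStep)) {
      for (i in seq_len(n - 1L)) {
        fi <- f[i]
        lo <- fi - maxStep; if (lo < fLo) lo <- fLo
        hi <- fi + maxStep; if (hi > fHi) hi <- fHi
        if (f[i + 1L] < lo) f[i + 1L] <- lo
        else if (f[i + 1L] > hi) f[i + 1L] <- hi
      }
    }
  }
  f
}

#' @describeIn generateFMFunction instantaneous frequencies (Hz per frame)
#' @param fm an [FMFunction-class]
#' @export
fmFrequencies <- function(fm) fm@freq

setMethod("show", "FMFunction", function(object) {
  cat(sprintf(
    "FMFunction: %d frames @ %g fps, band %s [%g, %g] Hz, seed %d\n",
    length(object@freq), object@frameRate, object@band@name,
    min(object@freq), max(object@freq), object@seed))
})

#' Convert an FM function to a contrast (luminance) timecourse
#'
#' The unwrapped phase is the cumulative integral of the instantaneous
#' frequency (computed on an 8x oversampled grid to avoid integration
#' aliasing near 20 Hz, then decimated back to frames), and luminance
#' follows `lumMin + (lumMax - lumMin) * (1 + sin(phase)) / 2`.
#'
#' @param fm an [FMFunction-class]
#' @param lumMin,lumMax patch peak-luminance bounds in cd/m2
#'   (defaults 7.5 and 29.1)
#' @param phase0 initial phase in radians
#' @param background background luminance in cd/m2 (default 6.5)
#' @return a [ContrastTimecourse-class]
#' @export
fmToCMF <- function(fm, lumMin = 7.5, lumMax = 29.1, phase0 = 0,
                    background = 6.5) {
  if (lumMin >= lumMax) stop("lumMin must be < lumMax")
  over <- 8L
  fsFine <- fm@frameRate * over
  nFine <- length(fm@freq) * over
  tFine <- (seq_len(nFine) - 1L) / fsFine
  fFine <- approx(fm@t, fm@freq, xout = tFine, rule = 2)$y
  ## phase at sample k is the integral up to (not including) sample k
  phFine <- phase0 + 2 * pi * c(0, cumsum(fFine[-nFine])) / fsFine
  idx <- seq(1L, nFine, by = over)
  phase <- phFine[idx]
  lum <- lumMin + (lumMax - lumMin) * (1 + sin(phase)) / 2
  new("ContrastTimecourse", t = fm@t, phase = phase, luminance = lum,
      lumMin = lumMin, lumMax = lumMax, background = background)
}

setMethod("show", "ContrastTimecourse", function(object) {
  cat(sprintf(
    "ContrastTimecourse: %d frames, luminance [%g, %g] cd/m2 (bounds %g-%g)\n",
    length(object@luminance), min(object@luminance), max(object@luminance),
    object@lumMin, object@lumMax))
})

#' Generate a decorrelated FM-function pair
#'
#' Rejection-samples two FM functions until the Pearson correlation of
#' their instantaneous-frequency traces satisfies `|r| < rMax`, mirroring
#' the decorrelation control applied to concurrently presented stimuli.
#'
#' @inheritParams generateFMFunction
#' @param rMax correlation bound, in (0, 1) (default 0.05)
#' @param maxTries rejection-sampling budget (default 1000)
#' @param seedLeft,seedRight optional explicit member seeds (testing hook);
#'   when given, only that single candidate pair is evaluated per try.
#' @return list with elements `left`, `right` (both [FMFunction-class]),
#'   `r` (achieved correlation) and `tries`
#' @export
generateDecorrelatedPair <- function(band, duration = 3.5, frameRate = 100,
                                     rMax = 0.05, seed = 1L,
                                     maxTries = 1000L,
                                     seedLeft = NULL, seedRight = NULL) {
  if (rMax <= 0 || rMax >= 1) stop("rMax must be in (0, 1)")
  bestR <- Inf
  for (try in seq_len(maxTries)) {
    sL <- if (is.null(seedLeft)) childSeed(seed, 2L * try) else seedLeft
    sR <- if (is.null(seedRight)) childSeed(seed, 2L * try + 1L) else seedRight
    fL <- .fmTrajectory(band, duration, frameRate, sL)
    fR <- .fmTrajectory(band, duration, frameRate, sR)
    r <- if (sd(fL) == 0 || sd(fR) == 0) 0 else cor(fL, fR)
    # constant traces carry no correlation
    if (abs(r) < abs(bestR)) bestR <- r
    if (abs(r) < rMax)
      return(list(left = generateFMFunction(band, duration, frameRate, sL),
                  right = generateFMFunction(band, duration, frameRate, sR),
                  r = r, tries = try))
  }
  stop(sprintf(
    "decorrelation |r| < %g not achieved in %d tries (best |r| = %.4f)",
    rMax, maxTries, abs(bestR)))
}

#' Place target/distracter events across trials
#'
#' Transient events occur in one third of all trials, at most twice per
#' trial with a minimum inter-onset interval, and always fall completely
#' inside the stimulation window.
#'
#' @param nTrials number of trials
#' @param pEventTrial probability that a trial contains events (default 1/3)
#' @param duration stimulation duration in s (default 3.5)
#' @param minGap minimum inter-onset interval in s (default 0.8)
#' @param eventDur event duration in s (default 0.3)
#' @param seed integer RNG seed
#' @return list of per-trial data.frames (kind, onset, duration)
#' @export
placeEvents <- function(nTrials, pEventTrial = 1 / 3, duration = 3.5,
                        minGap = 0.8, eventDur = 0.3, seed = 1L) {
  if (duration <= eventDur) stop("duration must exceed event duration")
  maxOnset <- duration - eventDur
  if (pEventTrial > 0 && maxOnset < minGap)
    stop("window too short to ever place two events with the required gap")
  withSeed(seed, {
    lapply(seq_len(nTrials), function(i) {
      if (runif(1) >= pEventTrial)
        return(data.frame(kind = character(0), onset = numeric(0),
                          duration = numeric(0)))
      nEv <- sample(1:2, 1L)
      if (nEv == 1L) {
        on <- runif(1, 0, maxOnset)
      } else {
        ## uniform over {0 <= a, a + minGap <= b <= maxOnset}
        u <- sort(runif(2, 0, maxOnset - minGap))
        on <- c(u[1], u[2] + minGap)
      }
      data.frame(kind = sample(c("target", "distracter"), nEv,
                               replace = TRUE),
                 onset = on, duration = eventDur)
    })
  })
}

#' Generate a complete stimulation trial
#'
#' Convenience constructor assembling a [TrialSpec-class]: a decorrelated
#' FM pair, their contrast timecourses with independent uniform initial
#' phases, and optional transient events.
#'
#' @inheritParams generateDecorrelatedPair
#' @param attendedSide "left" or "right"
#' @param events per-trial event data.frame (e.g. one element of
#'   [placeEvents()]); empty by default
#' @export
generateTrial <- function(band, attendedSide = "left", duration = 3.5,
                          frameRate = 100, rMax = 0.05, seed = 1L,
                          maxTries = 1000L, events = NULL) {
  pair <- generateDecorrelatedPair(band, duration, frameRate, rMax, seed,
                                   maxTries)
  ph <- withSeed(childSeed(seed, 999L), runif(2, 0, 2 * pi))
  if (is.null(events))
    events <- data.frame(kind = character(0), onset = numeric(0),
                         duration = numeric(0))
  new("TrialSpec", condition = band@name, attendedSide = attendedSide,
      fmLeft = pair$left, fmRight = pair$right,
      cmfLeft = fmToCMF(pair$left, phase0 = ph[1]),
      cmfRight = fmToCMF(pair$right, phase0 = ph[2]),
      events = events)
}

setMethod("show", "TrialSpec", function(object) {
  cat(sprintf(
    "TrialSpec: condition '%s', attend %s, %d event(s), %g s stimulation\n",
    object@condition, object@attendedSide, nrow(object@events),
    length(object@fmLeft@t) / object@fmLeft@frameRate))
})

## Shape-preserving (Fritsch-Carlson) monotone cubic Hermite
## interpolation on an equispaced knot grid; vectorized evaluation.
## Equivalent to stats::splinefun(method = "monoH.FC") for these knots,
## implemented directly because the trajectory generator evaluates it in
## a rejection-sampling hot loop.
.monoCubic <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  delta <- diff(yk) / h
  m <- c(delta[1], (delta[-1] + delta[-(n - 1)]) / 2, delta[n - 1])
  ## Fritsch-Carlson limiter
  for (i in seq_len(n - 1)) {
    if (delta[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / delta[i]
      b <- m[i + 1] / delta[i]
      r <- a^2 + b^2
      if (r > 9) {
        tau <- 3 / sqrt(r)
        m[i] <- tau * a * delta[i]
        m[i + 1] <- tau * b * delta[i]
      }
    }
  }
  i <- pmin(pmax(findInterval(xout, xk), 1L), n - 1L)
  t <- (xout - xk[i]) / h[i]
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * yk[i] + h10 * h[i] * m[i] + h01 * yk[i + 1] + h11 * h[i] * m[i + 1]
}

## single-FM constraint checks shared by validateStimulus
.fmViolations <- function(fm, label) {
  out <- list()
  band <- fm@band
  bad <- which(fm@freq < band@fLo - 1e-9 | fm@freq > band@fHi + 1e-9)
  if (length(bad))
    out[[length(out) + 1L]] <- data.frame(
      constraint = "band_containment", side = label, frame = bad[1],
      detail = sprintf("%d frames outside [%g, %g] Hz", length(bad),
                       band@fLo, band@fHi))
  rate <- abs(diff(fm@freq)) * fm@frameRate
  bad <- which(rate > bandwidth(band) + 1e-9)
  if (length(bad))
    out[[length(out) + 1L]] <- data.frame(
      constraint = "rate_limit", side = label, frame = bad[1],
      detail = sprintf("max rate %.3f Hz/s exceeds %g Hz/s", max(rate),
                       bandwidth(band)))
  out
}

.cmfViolations <- function(cmf, freqMax, frameRate, label) {
  out <- list()
  bad <- which(cmf@luminance < cmf@lumMin - 1e-9 |
               cmf@luminance > cmf@lumMax + 1e-9)
  if (length(bad))
    out[[length(out) + 1L]] <- data.frame(
      constraint = "luminance_bounds", side = label, frame = bad[1],
      detail = sprintf("luminance outside [%g, %g]", cmf@lumMin, cmf@lumMax))
  ## worst-case sampling miss of the sinusoid extremes at the highest rate
  amp <- cmf@lumMax - cmf@lumMin
  tol <- amp * (1 - cos(pi * freqMax / frameRate)) / 2 + 1e-6
  if (min(cmf@luminance) > cmf@lumMin + tol ||
      max(cmf@luminance) < cmf@lumMax - tol)
    out[[length(out) + 1L]] <- data.frame(
      constraint = "luminance_attainment", side = label, frame = NA_integer_,
      detail = "luminance does not attain its bounds over the trial")
  if (any(diff(cmf@phase) <= 0))
    out[[length(out) + 1L]] <- data.frame(
      constraint = "phase_monotonicity", side = label,
      frame = which(diff(cmf@phase) <= 0)[1],
      detail = "phase not strictly increasing")
  out
}

#' Validate a stimulation trial against all stimulus constraints
#'
#' Checks band containment, the one-bandwidth-per-second rate limit,
#' luminance bounds and attainment, phase monotonicity, FM-pair
#' decorrelation, and event-placement rules.
#'
#' @param trial a [TrialSpec-class]
#' @param rMax decorrelation bound (default 0.05)
#' @return data.frame of violations (constraint, side, frame, detail);
#'   zero rows when every constraint holds
#' @export
validateStimulus <- function(trial, rMax = 0.05) {
  out <- c(.fmViolations(trial@fmLeft, "left"),
           .fmViolations(trial@fmRight, "right"),
           .cmfViolations(trial@cmfLeft, max(trial@fmLeft@freq),
                          trial@fmLeft@frameRate, "left"),
           .cmfViolations(trial@cmfRight, max(trial@fmRight@freq),
                          trial@fmRight@frameRate, "right"))
  if (sd(trial@fmLeft@freq) > 0 && sd(trial@fmRight@freq) > 0) {
    r <- cor(trial@fmLeft@freq, trial@fmRight@freq)
    if (abs(r) >= rMax)
      out[[length(out) + 1L]] <- data.frame(
        constraint = "decorrelation", side = "pair", frame = NA_integer_,
        detail = sprintf("|r| = %.3f >= %g", abs(r), rMax))
  }
  ev <- trial@events
  dur <- length(trial@fmLeft@t) / trial@fmLeft@frameRate
  if (nrow(ev) > 2L)
    out[[length(out) + 1L]] <- data.frame(
      constraint = "event_count", side = "events", frame = NA_integer_,
      detail = sprintf("%d events exceed the maximum of 2", nrow(ev)))
  if (nrow(ev) == 2L && diff(sort(ev$onset)) < 0.8 - 1e-9)
    out[[length(out) + 1L]] <- data.frame(
      constraint = "event_gap", side = "events", frame = NA_integer_,
      detail = "inter-onset interval below 0.8 s")
  if (nrow(ev) > 0L && any(ev$onset < 0 | ev$onset + ev$duration > dur))
    out[[length(out) + 1L]] <- data.frame(
      constraint = "event_window", side = "events", frame = NA_integer_,
      detail = "event extends outside the stimulation window")
  if (length(out) == 0L)
    return(data.frame(constraint = character(0), side = character(0),
                      frame = integer(0), detail = character(0)))
  do.call(rbind, out)
}
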