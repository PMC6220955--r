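#' Stimulus frequency band
#'
#' Frequency band of the quasi-periodic contrast modulation. The three
#' presets used throughout are theta (4-7 Hz), alpha (8-13 Hz) and beta
#' (14-20 Hz); the permitted rate of change of the instantaneous frequency
#' is one bandwidth per second.
#'
#' @slot name band label ("theta", "alpha", "beta" or custom)
#' @slot fLo lower band edge (Hz)
#' @slot fHi upper band edge (Hz)
#' @export
setClass("StimulusBand",
  representation(name = "character", fLo = "numeric", fHi = "numeric"),
  validity = function(object) {
    if (length(object@fLo) != 1L || length(object@fHi) != 1L)
      return("fLo and fHi must be scalars")
    if (object@fLo > object@fHi) return("fLo must be <= fHi")
    if (object@fLo <= 0) return("band edges must be positive")
    TRUE
  })

#' Frequency-modulation function
#'
#' Instantaneous-frequency trajectory of one stimulus on the display frame
#' grid. The trajectory wanders randomly inside its band under the
#' one-bandwidth-per-second rate-of-change constraint.
#'
#' @slot t frame times (s)
#' @slot freq instantaneous frequency per frame (Hz)
#' @slot band the generating [StimulusBand-class]
#' @slot frameRate display frame rate (frames/s)
#' @slot seed RNG seed used to generate the trajectory
#' @export
setClass("FMFunction",
  representation(t = "numeric", freq = "numeric", band = "StimulusBand",
                 frameRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@t) != length(object@freq))
      return("t and freq must have equal length")
    TRUE
  })

#' Contrast (peak-luminance) timecourse
#'
#' Luminance modulation driven by an FM function: the unwrapped phase is the
#' integral of the instantaneous frequency and luminance follows a sinusoid
#' between \code{lumMin} and \code{lumMax}.
#'
#' @slot t frame times (s)
#' @slot phase unwrapped phase (rad), strictly increasing
#' @slot luminance patch peak luminance per frame (cd/m2)
#' @slot lumMin,lumMax luminance bounds (cd/m2)
#' @slot background background luminance (cd/m2)
#' @export
setClass("ContrastTimecourse",
  representation(t = "numeric", phase = "numeric", luminance = "numeric",
                 lumMin = "numeric", lumMax = "numeric",
                 background = "numeric"),
  validity = function(object) {
    if (length(object@t) != length(object@luminance) ||
        length(object@t) != length(object@phase))
      return("t, phase, luminance must have equal length")
    if (object@lumMin >= object@lumMax) return("lumMin must be < lumMax")
    TRUE
  })

#' Single-trial stimulus specification
#'
#' Two concurrently presented, decorrelated quasi-periodic stimuli plus the
#' target/distracter events of one trial.
#'
#' @slot condition band label of the stimulation condition
#' @slot attendedSide "left" or "right"
#' @slot fmLeft,fmRight FM functions of the two stimuli
#' @slot cmfLeft,cmfRight their contrast timecourses
#' @slot events data.frame with columns kind, onset, duration
#' @export
setClass("TrialSpec",
  representation(condition = "character", attendedSide = "character",
                 fmLeft = "FMFunction", fmRight = "FMFunction",
                 cmfLeft = "ContrastTimecourse",
                 cmfRight = "ContrastTimecourse",
                 events = "data.frame"),
  validity = function(object) {
    if (!object@attendedSide %in% c("left", "right"))
      return("attendedSide must be 'left' or 'right'")
    TRUE
  })

#' Electrode montage on the unit sphere
#'
#' Channel labels, 3-D unit-sphere positions and the two laterally
#' symmetric parieto-occipital channel clusters used in the alpha analyses.
#'
#' @slot labels channel labels
#' @slot positions n x 3 matrix of unit-norm positions
#'   (x: left-/right+, y: posterior-/anterior+, z: up)
#' @slot leftCluster,rightCluster labels of the two analysis clusters
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix",
                 leftCluster = "character", rightCluster = "character"),
  validity = function(object) {
    if (nrow(object@positions) != length(object@labels))
      return("positions must have one row per label")
    r <- sqrt(rowSums(object@positions^2))
    if (any(abs(r - 1) > 1e-6))
      return("positions must be normalized to unit radius")
    if (length(intersect(object@leftCluster, object@rightCluster)) > 0L)
      return("clusters must be disjoint")
    if (!all(c(object@leftCluster, object@rightCluster) %in% object@labels))
      return("cluster labels must be montage channels")
    TRUE
  })

#' Ground-truth generator parameters of one simulated subject
#'
#' @slot iafTrue intrinsic alpha peak frequency (Hz), within 6-14
#' @slot alphaAmp alpha oscillator amplitude (a.u., >= 0)
#' @slot attnModulation contralateral alpha suppression per hemisphere (dB)
#' @slot noiseExponent 1/f background slope
#' @slot noiseAmp background noise amplitude (a.u.)
#' @slot driveSnr amplitude of the stimulus-locked frequency-following
#'   component (a.u.)
#' @slot entrainCoupling Adler phase-coupling strength epsilon (rad/s),
#'   0 disables entrainment
#' @slot behaviorIntercept,behaviorSlope logit-linear accuracy model
#' @export
setClass("SubjectParams",
  representation(iafTrue = "numeric", alphaAmp = "numeric",
                 attnModulation = "numeric", noiseExponent = "numeric",
                 noiseAmp = "numeric", driveSnr = "numeric",
                 entrainCoupling = "numeric",
                 behaviorIntercept = "numeric", behaviorSlope = "numeric"),
  validity = function(object) {
    if (object@iafTrue < 6 || object@iafTrue > 14)
      return("iafTrue must lie in [6, 14] Hz")
    if (object@alphaAmp < 0) return("alphaAmp must be >= 0")
    if (object@entrainCoupling < 0) return("entrainCoupling must be >= 0")
    TRUE
  })

#' Synthetic multi-channel EEG recording
#'
#' @slot data channels x samples matrix (uV)
#' @slot fs sampling rate (Hz)
#' @slot montage the [Montage-class]
#' @slot trials list of [TrialSpec-class] (empty for peri recordings)
#' @slot onsets stimulation-onset sample index per trial
#' @slot subject generating [SubjectParams-class]
#' @slot segmentKind "during" or "peri"
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", montage = "Montage",
                 trials = "list", onsets = "integer",
                 subject = "SubjectParams", segmentKind = "character"),
  validity = function(object) {
    if (nrow(object@data) != length(object@montage@labels))
      return("data must have one row per montage channel")
    if (anyNA(object@data)) return("data must not contain NaN/NA")
    if (length(object@onsets) != length(object@trials))
      return("one onset per trial required")
    if (!object@segmentKind %in% c("during", "peri"))
      return("segmentKind must be 'during' or 'peri'")
    TRUE
  })

#' Set of windowed 1-s epochs
#'
#' @slot data epochs x channels x samples array
#' @slot fs sampling rate (Hz)
#' @slot montage the [Montage-class]
#' @slot info per-epoch provenance (trial, offset, condition, attendedSide,
#'   hasEvent)
#' @slot scale "potential" (uV) or "scd" after the surface-Laplacian
#'   transform
#' @export
setClass("EpochSet",
  representation(data = "array", fs = "numeric", montage = "Montage",
                 info = "data.frame", scale = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be epochs x channels x samples")
    if (d[2] != length(object@montage@labels))
      return("channel dimension must match montage")
    if (d[3] != round(object@fs))
      return("epoch length must be exactly 1 s")
    if (nrow(object@info) != d[1])
      return("info must have one row per epoch")
    TRUE
  })

#' Per-channel power spectrum on a regular frequency grid
#'
#' @slot freqs frequency grid (Hz), strictly increasing, 0.5 Hz spacing by
#'   construction
#' @slot values channels x frequencies matrix of power (raw) or log-power
#'   (dB = 10*log10(raw))
#' @slot scale "raw" or "dB"
#' @slot channels channel labels (rows of values)
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", values = "matrix", scale = "character",
                 channels = "character"),
  validity = function(object) {
    if (ncol(object@values) != length(object@freqs))
      return("values must have one column per frequency")
    if (nrow(object@values) != length(object@channels))
      return("values must have one row per channel")
    if (any(diff(object@freqs) <= 0))
      return("freqs must be strictly increasing")
    if (!object@scale %in% c("raw", "dB"))
      return("scale must be 'raw' or 'dB'")
    TRUE
  })

#' Cluster-based permutation test result
#'
#' @slot clusters data.frame: id, sign, nChannels, stat (sum of paired t),
#'   p (two-sided corrected)
#' @slot members list of channel-label vectors, one per cluster
#' @slot nPerm number of random sign-flip permutations
#' @slot neighborMeanDegree mean degree of the channel neighbour graph
#' @export
setClass("ClusterTestResult",
  representation(clusters = "data.frame", members = "list",
                 nPerm = "integer", neighborMeanDegree = "numeric"))

#' Repeated-measures ANOVA result with Greenhouse-Geisser correction
#'
#' @slot table per-effect data.frame: effect, dfEff, dfErr, F, p, epsilonGG,
#'   pGG, omegaP2, omegaTruncated
#' @slot nSubjects number of subjects
#' @export
setClass("AnovaResult",
  representation(table = "data.frame", nSubjects = "integer"))

#' JZS Bayes-factor ANOVA result
#'
#' @slot table per-term data.frame: term, bf10, bf01, mcErrorPct, flagged
#' @slot rFixed JZS prior scale of fixed effects
#' @slot rRandom prior scale of the random subject factor
#' @slot nMc Monte-Carlo iterations
#' @export
setClass("BayesAnovaResult",
  representation(table = "data.frame", rFixed = "numeric",
                 rRandom = "numeric", nMc = "numeric"))

#' Robust linear regression fit
#'
#' @slot beta0,beta1 intercept and slope of the bisquare IRLS fit
#' @slot r2 weighted goodness of fit
#' @slot fStat,pValue F-test of the fit against a constant model
#' @slot ci data.frame of bootstrap CIs (one row per coefficient), empty if
#'   no bootstrap was requested
#' @slot outliersRemoved indices removed by Cook's-distance screening
#' @slot n number of points entering the robust fit
#' @slot weights final bisquare weights
#' @export
setClass("RegressionFit",
  representation(beta0 = "numeric", beta1 = "numeric", r2 = "numeric",
                 fStat = "numeric", pValue = "numeric", ci = "data.frame",
                 outliersRemoved = "integer", n = "integer",
                 weights = "numeric"))

#' Study configuration
#'
#' All parameters of a simulated experiment: cohort, montage, trial counts,
#' generator settings and analysis constants. Create with [studyConfig()].
#'
#' @slot params named list of configuration entries
#' @export
setClass("StudyConfig", representation(params = "list"))

#' Full study report
#'
#' Output of [runStudy()]: alpha profiles and the complete inference battery.
#'
#' @slot profiles AlphaProfile table (subject, condition, iaf, iap,
#'   lateralization)
#' @slot clusterTest [ClusterTestResult-class] of the attention topography
#'   contrast
#' @slot anova [AnovaResult-class] hemisphere x position x frequency
#' @slot bayesAnova [BayesAnovaResult-class]
#' @slot contrasts Holm-corrected attended-minus-unattended contrasts
#' @slot regressions list of [RegressionFit-class] (during ~ peri, per
#'   measure and condition)
#' @slot slopeDiffs data.frame of pairwise slope-difference CIs
#' @slot friedman Friedman test on |IAF - 10.5| distances
#' @slot behavior behavioural regression results
#' @slot config the generating [StudyConfig-class]
#' @export
setClass("StudyReport",
  representation(profiles = "data.frame", clusterTest = "ClusterTestResult",
                 anova = "AnovaResult", bayesAnova = "BayesAnovaResult",
                 contrasts = "data.frame", regressions = "list",
                 slopeDiffs = "data.frame", friedman = "list",
                 behavior = "list", config = "StudyConfig"))
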