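## End-to-end orchestration: simulate a cohort, their stimuli and EEG,
## run the spectral decomposition, extract alpha observables and apply
## the complete inference battery.

#' Build a study configuration
#'
#' All simulation and analysis constants of a synthetic study. Defaults
#' follow the standard design for this paradigm: 17 subjects, 512 Hz, 48 trials
#' per frequency condition of 0.5 s cue + 3.5 s stimulation with 25%
#' simulated rejection, 96 s of peri-stimulation rest, group alpha band
#' 8-12 Hz, IAF +/- 1 Hz individual band, 1000 cluster permutations,
#' 10000 bootstrap resamples, 1e5 Monte-Carlo iterations at JZS scale 0.5.
#'
#' @param ... overrides of the default entries (see Details in the
#'   package vignette); unknown names raise an error
#' @return a [StudyConfig-class]
#' @export
studyConfig <- function(...) {
  defaults <- list(
    nSubjects = 17L, seed = 1L, nChannels = 32L, fs = 512,
    frameRate = 100,
    conditions = c("theta", "alpha", "beta"),
    trialsPerCondition = 48L, rejectFraction = 0.25,
    periDuration = 96,
    attnModulation = 2, driveSnr = 0.2,
    noiseAmp = 1, noiseExponent = 1,
    entrainCoupling = c(theta = 0, alpha = 0, beta = 0),
    behaviorIntercept = 1.2,
    behaviorSlope = c(theta = 0, alpha = -0.664, beta = 0),
    behaviorNoiseSd = 0.3,
    alphaBand = c(8, 12), iapHalfwidth = 1, iafSearch = c(6, 14),
    scdEnabled = TRUE, scdLambda = 1e-4,
    nPerm = 1000L, clusterAlpha = 0.05,
    nBoot = 10000L, nMc = 1e5, rFixed = 0.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  new("StudyConfig", params = defaults)
}

#' @describeIn studyConfig retrieve one configuration entry
#' @param config a [StudyConfig-class]
#' @param name entry name
#' @export
configParam <- function(config, name) {
  if (!name %in% names(config@params)) stop("no config entry '", name, "'")
  config@params[[name]]
}

setMethod("show", "StudyConfig", function(object) {
  p <- object@params
  cat(sprintf(
    "StudyConfig: %d subjects, %d channels, %d trials/condition, seed %d\n",
    p$nSubjects, p$nChannels, p$trialsPerCondition, p$seed))
})

## subset an EpochSet by epoch indices
subsetEpochs <- function(epochs, idx) {
  new("EpochSet", data = epochs@data[idx, , , drop = FALSE],
      fs = epochs@fs, montage = epochs@montage,
      info = epochs@info[idx, , drop = FALSE], scale = epochs@scale)
}

## mean log-power per channel within a frequency band -> named vector
bandTopography <- function(psDb, band) {
  sel <- psDb@freqs >= band[1] & psDb@freqs <= band[2]
  v <- rowMeans(psDb@values[, sel, drop = FALSE])
  names(v) <- psDb@channels
  v
}

## simulate and decompose one subject: spectra per condition x side,
## pooled per condition, and peri
.subjectSpectra <- function(subj, montage, cfg, seedBase) {
  p <- cfg@params
  out <- list(bySide = list(), byCond = list())
  for (ci in seq_along(p$conditions)) {
    cond <- p$conditions[ci]
    band <- stimulusBand(cond)
    nT <- p$trialsPerCondition
    evSeed <- childSeed(seedBase, 100L + ci)
    events <- placeEvents(nT, duration = 3.5, seed = evSeed)
    sides <- rep(c("left", "right"), length.out = nT)
    trials <- lapply(seq_len(nT), function(k)
      generateTrial(band, attendedSide = sides[k],
                    frameRate = p$frameRate,
                    seed = childSeed(seedBase, 1000L * ci + k),
                    events = events[[k]]))
    ## simulated artifact rejection; every attended side must retain at
    ## least two event-free trials for its per-side spectra
    keep <- withSeed(childSeed(seedBase, 200L + ci),
                     runif(nT) >= p$rejectFraction)
    eventFree <- vapply(events, nrow, 0L) == 0L
    clearEvents <- function(j) {
      events[[j]] <<- events[[j]][0, ]
      trials[[j]]@events <<- trials[[j]]@events[0, ]
      eventFree[j] <<- TRUE
    }
    for (side in c("left", "right")) {
      idx <- which(sides == side)
      need <- function() 2L - sum(keep[idx] & eventFree[idx])
      if (need() > 0) {  # promote rejected event-free trials
        pool <- idx[!keep[idx] & eventFree[idx]]
        keep[utils::head(pool, need())] <- TRUE
      }
      if (need() > 0) {  # clear events on kept trials
        for (j in utils::head(idx[keep[idx] & !eventFree[idx]], need()))
          clearEvents(j)
      }
      if (need() > 0) {  # last resort: promote and clear
        for (j in utils::head(idx[!keep[idx]], need())) {
          keep[j] <- TRUE
          if (!eventFree[j]) clearEvents(j)
        }
      }
    }
    trials <- trials[keep]
    eps <- unname(p$entrainCoupling[cond])
    if (is.na(eps)) eps <- 0
    subjC <- subj
    subjC@entrainCoupling <- eps
    rec <- simulateRecording(subjC, trials, montage, fs = p$fs,
                             seed = childSeed(seedBase, 300L + ci))
    ep <- epochData(rec, excludeEventTrials = TRUE)
    if (p$scdEnabled) ep <- scalpCurrentDensity(ep, lambda = p$scdLambda)
    bySide <- list()
    nEp <- integer(0)
    for (side in c("left", "right")) {
      idx <- which(ep@info$attendedSide == side)
      bySide[[side]] <- if (length(idx))
        powerSpectrum(subsetEpochs(ep, idx)) else NULL
      nEp[side] <- length(idx)
    }
    out$bySide[[cond]] <- bySide
    ## pooled condition spectrum = epoch-weighted mean of the side spectra
    pL <- bySide$left; pR <- bySide$right
    out$byCond[[cond]] <- new("PowerSpectrum", freqs = pL@freqs,
      values = (nEp["left"] * pL@values + nEp["right"] * pR@values) /
        sum(nEp),
      scale = "raw", channels = pL@channels)
  }
  recPeri <- simulatePeri(subj, duration = p$periDuration, montage,
                          fs = p$fs, seed = childSeed(seedBase, 400L))
  epPeri <- epochData(recPeri)
  if (p$scdEnabled) epPeri <- scalpCurrentDensity(epPeri,
                                                  lambda = p$scdLambda)
  out$peri <- powerSpectrum(epPeri)
  out
}

## derive left/right analysis clusters from the cluster-test result,
## falling back to the montage-defined clusters
.deriveClusters <- function(ct, montage) {
  sig <- which(ct@clusters$p < 0.05)
  if (length(sig) >= 2) {
    xmeans <- vapply(sig, function(i) {
      idx <- match(ct@members[[i]], montage@labels)
      mean(montage@positions[idx, 1])
    }, 0)
    l <- sig[which.min(xmeans)]
    r <- sig[which.max(xmeans)]
    if (l != r)
      return(list(left = ct@members[[l]], right = ct@members[[r]],
                  functional = TRUE))
  }
  list(left = montage@leftCluster, right = montage@rightCluster,
       functional = FALSE)
}

#' Run a complete synthetic study
#'
#' Simulates the cohort, stimuli and EEG described by `config`, computes
#' spectra, derives the attention-lateralization topographies and the
#' analysis clusters, extracts IAF/IAP/lateralization profiles, and runs
#' the inference battery: cluster-based permutation test,
#' hemisphere x position x frequency repeated-measures ANOVA with
#' Greenhouse-Geisser correction, JZS Bayes-factor ANOVA, Holm-corrected
#' attended-vs-unattended contrasts, robust during-on-peri regressions
#' with BCa intervals and pairwise slope differences, a Friedman test on
#' the |IAF - 10.5 Hz| distances, and the behavioural regressions.
#'
#' @param config a [StudyConfig-class]
#' @param verbose print stage progress (default FALSE)
#' @return a [StudyReport-class]
#' @export
runStudy <- function(config, verbose = FALSE) {
  p <- config@params
  say <- function(...) if (verbose) message(...)
  montage <- makeMontage(p$nChannels)
  cohort <- makeCohort(p$nSubjects, seed = childSeed(p$seed, 1L),
                       attnModulation = p$attnModulation,
                       driveSnr = p$driveSnr, noiseAmp = p$noiseAmp,
                       noiseExponent = p$noiseExponent,
                       behaviorIntercept = p$behaviorIntercept)
  nS <- p$nSubjects
  conds <- p$conditions

  say("simulating and decomposing ", nS, " subjects")
  spectra <- lapply(seq_len(nS), function(s)
    .subjectSpectra(cohort[[s]], montage, config,
                    seedBase = childSeed(p$seed, 10L + s)))

  ## attention topographies pooled over conditions (dB, group alpha band)
  nCh <- length(montage@labels)
  topoL <- matrix(0, nS, nCh)
  topoR <- matrix(0, nS, nCh)
  for (s in seq_len(nS)) {
    accL <- accR <- 0
    for (cond in conds) {
      accL <- accL + bandTopography(
        toLogPower(spectra[[s]]$bySide[[cond]]$left), p$alphaBand)
      accR <- accR + bandTopography(
        toLogPower(spectra[[s]]$bySide[[cond]]$right), p$alphaBand)
    }
    topoL[s, ] <- accL / length(conds)
    topoR[s, ] <- accR / length(conds)
  }
  say("cluster-based permutation test")
  ct <- clusterPermutationTest(topoL, topoR, montage, nPerm = p$nPerm,
                               clusterAlpha = p$clusterAlpha,
                               seed = childSeed(p$seed, 2L))
  cl <- .deriveClusters(ct, montage)
  clusterCh <- c(cl$left, cl$right)

  ## ANOVA cells: hemisphere x position (contra/ipsi to attention) x freq
  cells <- list()
  for (s in seq_len(nS)) for (cond in conds) {
    for (side in c("left", "right")) {
      psDb <- toLogPower(spectra[[s]]$bySide[[cond]][[side]])
      topo <- bandTopography(psDb, p$alphaBand)
      for (hemi in c("left", "right")) {
        chs <- if (hemi == "left") cl$left else cl$right
        pos <- if (hemi == side) "ipsi" else "contra"
        cells[[length(cells) + 1L]] <- data.frame(
          subject = s, hemisphere = hemi, position = pos,
          frequency = cond, attendedSide = side,
          value = mean(topo[chs]))
      }
    }
  }
  cellDf <- do.call(rbind, cells)
  ## average the two attended sides mapping onto the same cell
  anovaDf <- stats::aggregate(value ~ subject + hemisphere + position +
                                frequency, data = cellDf, FUN = mean)
  say("repeated-measures ANOVA and Bayes factors")
  an <- rmAnovaGG(anovaDf, within = c("hemisphere", "position",
                                      "frequency"))
  bf <- jzsAnovaBF(anovaDf, within = c("hemisphere", "position",
                                       "frequency"),
                   rFixed = p$rFixed, nMc = p$nMc,
                   seed = childSeed(p$seed, 3L))

  ## attended-minus-unattended contrasts per hemisphere x condition
  ctr <- list()
  for (hemi in c("left", "right")) for (cond in conds) {
    att <- anovaDf$value[anovaDf$hemisphere == hemi &
                         anovaDf$position == "ipsi" &
                         anovaDf$frequency == cond]
    una <- anovaDf$value[anovaDf$hemisphere == hemi &
                         anovaDf$position == "contra" &
                         anovaDf$frequency == cond]
    tt <- stats::t.test(att - una)
    ctr[[length(ctr) + 1L]] <- data.frame(
      hemisphere = hemi, frequency = cond,
      meanDiff = mean(att - una), t = unname(tt$statistic),
      p = tt$p.value)
  }
  contrasts <- do.call(rbind, ctr)
  hb <- holmBonferroni(contrasts$p)
  contrasts$pHolm <- hb$pAdjusted
  contrasts$reject <- hb$reject

  ## alpha profiles (IAF, IAP, lateralization) per condition and peri
  say("alpha profiles")
  prof <- list()
  for (s in seq_len(nS)) {
    for (cond in c(conds, "peri")) {
      psRaw <- if (cond == "peri") spectra[[s]]$peri
               else spectra[[s]]$byCond[[cond]]
      psDb <- toLogPower(psRaw)
      iaf <- detectIAF(psRaw, channels = clusterCh,
                       searchLo = p$iafSearch[1],
                       searchHi = p$iafSearch[2])
      iap <- if (is.na(iaf)) NA_real_
             else computeIAP(psDb, iaf, channels = clusterCh,
                             halfwidth = p$iapHalfwidth)
      lat <- NA_real_
      if (cond != "peri" && !is.na(iaf)) {
        latBySide <- vapply(c("left", "right"), function(side) {
          psS <- toLogPower(spectra[[s]]$bySide[[cond]][[side]])
          contraCh <- if (side == "left") cl$right else cl$left
          ipsiCh <- if (side == "left") cl$left else cl$right
          lateralizationIndex(
            computeIAP(psS, iaf, channels = contraCh,
                       halfwidth = p$iapHalfwidth),
            computeIAP(psS, iaf, channels = ipsiCh,
                       halfwidth = p$iapHalfwidth))
        }, 0)
        lat <- mean(latBySide)
      }
      prof[[length(prof) + 1L]] <- alphaProfile(s, cond, iaf, iap, lat)
    }
  }
  profiles <- do.call(rbind, prof)
  noPeak <- unique(profiles$subject[is.na(profiles$iaf)])
  if (length(noPeak))
    message(length(noPeak), " subject(s) without a detectable alpha ",
            "peak excluded listwise from the regressions")
  complete <- setdiff(seq_len(nS), noPeak)

  ## during ~ peri regressions (IAF z-scored, IAP on raw dB values)
  say("during-on-peri regressions")
  getVals <- function(cond, what)
    profiles[[what]][profiles$condition == cond][complete]
  zs <- function(v) {  # centred only when the spread degenerates
    s <- sd(v)
    if (!is.finite(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  }
  regressions <- list()
  regData <- list()
  for (measure in c("iaf", "iap")) {
    periV <- getVals("peri", measure)
    for (cond in conds) {
      durV <- getVals(cond, measure)
      x <- if (measure == "iaf") zs(periV) else periV
      y <- if (measure == "iaf") zs(durV) else durV
      key <- paste(measure, cond, sep = ".")
      regData[[key]] <- list(x = x, y = y)
      regressions[[key]] <- robustFit(
        x, y, removeOutliers = FALSE, nBoot = p$nBoot, level = 0.95,
        seed = childSeed(p$seed, 40L + length(regressions)))
    }
  }
  ## pairwise slope differences at the Bonferroni-adjusted level
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  sd_rows <- list()
  for (measure in c("iaf", "iap")) for (pr in pairs) {
    a <- regData[[paste(measure, pr[1], sep = ".")]]
    b <- regData[[paste(measure, pr[2], sep = ".")]]
    res <- slopeDifferenceTest(a$x, a$y, b$x, b$y,
                               nBoot = p$nBoot,
                               seed = childSeed(p$seed,
                                                60L + length(sd_rows)))
    sd_rows[[length(sd_rows) + 1L]] <- data.frame(
      measure = measure, condA = pr[1], condB = pr[2],
      deltaBeta1 = res$deltaBeta1, lower = res$lower,
      upper = res$upper, level = res$level, reject = res$reject)
  }
  slopeDiffs <- do.call(rbind, sd_rows)

  ## Friedman test on |IAF - 10.5| across conditions and peri
  say("Friedman test on IAF distances")
  distMat <- sapply(c(conds, "peri"), function(cond)
    abs(getVals(cond, "iaf") - 10.5))
  fr <- friedmanTest(distMat)

  ## behaviour: logit accuracy ~ z-scored IAP per condition
  say("behavioural regressions")
  behavior <- list()
  for (cond in conds) {
    iapZ <- zs(getVals(cond, "iap"))
    slope <- unname(p$behaviorSlope[cond])
    if (is.na(slope)) slope <- 0
    acc <- simulateBehavior(NULL, iapZ,
                            seed = childSeed(p$seed,
                                             80L + match(cond, conds)),
                            noiseSd = p$behaviorNoiseSd,
                            intercept = p$behaviorIntercept,
                            slope = slope)
    perf <- zs(logitTransform(acc, nTrials = p$trialsPerCondition))
    behavior[[cond]] <- list(
      accuracy = acc,
      fit = robustFit(iapZ, perf, removeOutliers = TRUE,
                      nBoot = p$nBoot,
                      seed = childSeed(p$seed, 90L + match(cond, conds))))
  }

  new("StudyReport", profiles = profiles, clusterTest = ct, anova = an,
      bayesAnova = bf, contrasts = contrasts, regressions = regressions,
      slopeDiffs = slopeDiffs,
      friedman = c(fr, list(conditions = c(conds, "peri"))),
      behavior = behavior, config = config)
}

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n===========\n")
  show(object@config)
  cat("\nCluster test:\n"); show(object@clusterTest)
  cat("\n"); show(object@anova)
  cat("\n"); show(object@bayesAnova)
  cat("\nFriedman on |IAF - 10.5 Hz|: chi2 =",
      round(object@friedman$statistic, 3), ", df =", object@friedman$df,
      ", p =", signif(object@friedman$p.value, 3), "\n")
})

#' Signed IAF pull toward the alpha-stimulation centre frequency
#'
#' Quantifies whether IAF estimates during one stimulation condition moved
#' toward the 10.5 Hz centre of the alpha-band stimulation relative to the
#' peri-stimulation baseline. For every subject whose peri IAF is at least
#' `minDetuning` away from 10.5 Hz (detuned subjects are the only ones on
#' whom a pull is measurable), the signed movement
#' `sign(10.5 - IAF_peri) * (IAF_cond - IAF_peri)` is averaged; movements
#' toward (or past) the centre count positive. The statistic for a control
#' condition (default beta, which shares the estimation noise of a
#' during-stimulation measurement) is subtracted, so that under a
#' no-entrainment generator the expected value is zero.
#'
#' @param report a [StudyReport-class]
#' @param condition condition to evaluate (default "alpha")
#' @param reference control condition (default "beta")
#' @param minDetuning minimum |IAF_peri - 10.5| in Hz (default 0.5, one
#'   grid step)
#' @param centre stimulation centre frequency (default 10.5 Hz)
#' @return the pull statistic in Hz (positive = pulled toward the centre),
#'   or NA when fewer than two detuned subjects are available
#' @export
iafPullStatistic <- function(report, condition = "alpha",
                             reference = "beta", minDetuning = 0.5,
                             centre = 10.5) {
  pr <- report@profiles
  wide <- stats::reshape(pr[, c("subject", "condition", "iaf")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  peri <- wide$iaf.peri
  pull <- function(cond) {
    v <- wide[[paste0("iaf.", cond)]]
    far <- which(is.finite(peri) & abs(peri - centre) >= minDetuning &
                 is.finite(v))
    if (length(far) < 2) return(NA_real_)
    mean(sign(centre - peri[far]) * (v[far] - peri[far]))
  }
  pull(condition) - pull(reference)
}

#' Tabulate the during-on-peri regression parameters
#'
#' Formats the report's robust-regression fits as one row per measure and
#' condition with intercept, slope, their bootstrap CIs and goodness of
#' fit.
#'
#' @param report a [StudyReport-class]
#' @return data.frame (measure, condition, r2, beta0, beta0Lo, beta0Hi,
#'   beta1, beta1Lo, beta1Hi, fStat, p)
#' @export
compareRegressionTables <- function(report) {
  rows <- list()
  for (key in names(report@regressions)) {
    fit <- report@regressions[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ci <- fit@ci
    g <- function(coefName, col) {
      i <- which(ci$coef == coefName)
      if (length(i)) ci[[col]][i] else NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      measure = parts[1], condition = parts[2], r2 = fit@r2,
      beta0 = fit@beta0, beta0Lo = g("beta0", "lower"),
      beta0Hi = g("beta0", "upper"),
      beta1 = fit@beta1, beta1Lo = g("beta1", "lower"),
      beta1Hi = g("beta1", "upper"),
      fStat = fit@fStat, p = fit@pValue)
  }
  do.call(rbind, rows)
}
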