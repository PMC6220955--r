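makeTrials <- function(band = "alpha", n = 6, seedBase = 0) {
  sides <- rep(c("left", "right"), length.out = n)
  lapply(seq_len(n), function(k)
    generateTrial(stimulusBand(band), attendedSide = sides[k],
                  seed = seedBase + k))
}

clusterBandPower <- function(rec, montage, band = c(8, 12)) {
  ep <- epochData(rec, excludeEventTrials = FALSE)
  ps <- toLogPower(powerSpectrum(ep))
  sel <- ps@freqs >= band[1] & ps@freqs <= band[2]
  topo <- rowMeans(ps@values[, sel])
  c(left = mean(topo[match(leftCluster(montage), ps@channels)]),
    right = mean(topo[match(rightCluster(montage), ps@channels)]))
}

test_that("symmetric null generator balances the hemispheres", {
  m <- testMontage(16)
  trials <- makeTrials(n = 6)
  diffs <- vapply(1:10, function(s) {
    sp <- subjectParams(iafTrue = 10, alphaAmp = 4, attnModulation = 0)
    pw <- clusterBandPower(simulateRecording(sp, trials, m, seed = 50 + s), m)
    pw["left"] - pw["right"]
  }, 0)
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.25)
})

test_that("attention gains suppress the contralateral cluster", {
  m <- testMontage(16)
  trials <- makeTrials(n = 8)
  sp <- subjectParams(iafTrue = 10, alphaAmp = 4, attnModulation = 2)
  rec <- simulateRecording(sp, trials, m, seed = 9)
  ep <- epochData(rec, excludeEventTrials = FALSE)
  sel <- function(side) {
    idx <- which(ep@info$attendedSide == side)
    ps <- toLogPower(powerSpectrum(alphakit:::subsetEpochs(ep, idx)))
    fsel <- ps@freqs >= 8 & ps@freqs <= 12
    topo <- rowMeans(ps@values[, fsel])
    c(left = mean(topo[match(leftCluster(m), ps@channels)]),
      right = mean(topo[match(rightCluster(m), ps@channels)]))
  }
  attL <- sel("left")
  attR <- sel("right")
  ## ipsilateral enhancement, contralateral suppression, both hemispheres
  expect_gt(attL["left"], attR["left"])
  expect_gt(attR["right"], attL["right"])
})

test_that("doubling the alpha amplitude raises cluster alpha power 6 dB", {
  m <- testMontage(16)
  trials <- makeTrials(n = 6)
  pw <- lapply(c(8, 16), function(a) {
    sp <- subjectParams(iafTrue = 10, alphaAmp = a, attnModulation = 0,
                        noiseAmp = 0.1)
    ep <- epochData(simulateRecording(sp, trials, m, seed = 4),
                    excludeEventTrials = FALSE)
    ps <- powerSpectrum(ep)
    sel <- ps@freqs >= 9 & ps@freqs <= 11
    mean(ps@values[match(bothClusters(m), ps@channels), sel])
  })
  expect_equal(10 * log10(pw[[2]] / pw[[1]]), 6.02, tolerance = 0.1)
})

test_that("peri recordings epoch to the documented counts", {
  m <- testMontage(16)
  sp <- subjectParams(iafTrue = 10, alphaAmp = 4)
  rec <- simulatePeri(sp, duration = 96, montage = m, seed = 1)
  expect_equal(ncol(rec@data), 96 * 512)
  ep <- epochData(rec)
  expect_equal(dim(ep@data)[1], 191)  # (96 - 1) / 0.5 + 1
  expect_gte(dim(ep@data)[1], 102)
  expect_error(simulatePeri(sp, duration = 3, montage = m), "6 s")
})

test_that("peri spectrum recovers the true alpha frequency", {
  m <- testMontage(16)
  sp <- subjectParams(iafTrue = 10, alphaAmp = 6)
  rec <- simulatePeri(sp, duration = 24, montage = m, seed = 8)
  ps <- powerSpectrum(epochData(rec))
  avg <- channelAverage(ps, bothClusters(m))
  sel <- ps@freqs >= 8 & ps@freqs <= 12
  naive <- ps@freqs[sel][which.max(avg[sel])]
  expect_equal(naive, 10, tolerance = 0.5)
  expect_equal(detectIAF(ps, bothClusters(m)), 10, tolerance = 0.5)
})

test_that("recordings are reproducible from their seed", {
  m <- testMontage(16)
  trials <- makeTrials(n = 2)
  sp <- subjectParams(iafTrue = 9.5, alphaAmp = 4)
  r1 <- simulateRecording(sp, trials, m, seed = 12)
  r2 <- simulateRecording(sp, trials, m, seed = 12)
  expect_identical(r1@data, r2@data)
  p1 <- simulatePeri(sp, 12, m, seed = 5)
  p2 <- simulatePeri(sp, 12, m, seed = 5)
  expect_identical(p1@data, p2@data)
})

test_that("entrainment coupling pulls the measured IAF as the phase
           equation predicts", {
  m <- testMontage(16)
  band <- stimulusBand("alpha")
  trials <- makeTrials(n = 10)
  fs <- 512
  eps <- 2 * pi * 1.5
  iafTrue <- 9
  ## independent oracle: integrate the Adler equation on the actual
  ## attended stimulus phases and average the instantaneous frequency
  predicted <- mean(vapply(trials, function(tr) {
    cmf <- if (tr@attendedSide == "left") tr@cmfLeft else tr@cmfRight
    phiS <- alphakit:::resamplePhase(cmf, fs, round(3.5 * fs))
    sub <- 4
    phiF <- approx(seq_along(phiS), phiS,
                   xout = seq(1, length(phiS), by = 1 / sub))$y
    p <- 0
    dtf <- 1 / (fs * sub)
    for (k in seq_along(phiF))
      p <- p + (2 * pi * iafTrue + eps * sin(phiF[k] - p)) * dtf
    p / (2 * pi * 3.5)
  }, 0))
  expect_gte(predicted - iafTrue, 0.3)  # oracle itself shows a pull
  iafAt <- function(coupling) {
    sp <- subjectParams(iafTrue = iafTrue, alphaAmp = 5,
                        attnModulation = 0, entrainCoupling = coupling)
    rec <- simulateRecording(sp, trials, m, seed = 11)
    ps <- powerSpectrum(epochData(rec, excludeEventTrials = FALSE))
    detectIAF(ps, bothClusters(m))
  }
  base <- iafAt(0)
  pulled <- iafAt(eps)
  expect_equal(base, iafTrue, tolerance = 0.5)
  expect_gte(pulled - base, 0.5)
  expect_equal(pulled, predicted, tolerance = 0.75)
})

test_that("recordings round-trip through the text interchange format", {
  m <- testMontage(16)
  sp <- subjectParams(iafTrue = 9.5, alphaAmp = 4, entrainCoupling = 1)
  rec <- simulatePeri(sp, duration = 6, montage = m, seed = 2)
  path <- tempfile(fileext = ".csv")
  writeRecordingCSV(rec, path)
  df <- read.csv(path, check.names = FALSE)
  expect_identical(names(df), channelLabels(m))
  expect_equal(as.matrix(df), t(rec@data), tolerance = 1e-6,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$fs, 512)
  expect_equal(side$subject$iafTrue, 9.5)
  expect_equal(side$subject$entrainCoupling, 1)
  sfp <- tempfile(fileext = ".sfp")
  writeMontageSFP(m, sfp)
  pos <- read.table(sfp)
  expect_equal(pos$V1, channelLabels(m))
  expect_equal(as.matrix(pos[, 2:4]), channelPositions(m),
               tolerance = 1e-5, ignore_attr = TRUE)
  unlink(c(path, paste0(path, ".json"), sfp))
})

test_that("behavioural generator follows the logit-linear model", {
  iapZ <- seq(-2, 2, length.out = 16)
  ## null slope recovered within 2 SE
  acc <- simulateBehavior(NULL, iapZ, seed = 3, slope = 0,
                          noiseSd = 0.3)
  expect_true(all(acc > 0 & acc < 1))
  fit <- lm(qlogis(acc) ~ iapZ)
  expect_lt(abs(coef(fit)[2]), 2 * summary(fit)$coefficients[2, 2])
  ## saturation at extreme intercepts
  accHi <- simulateBehavior(NULL, iapZ, seed = 4, intercept = 30)
  expect_true(all(accHi > 0.999))
  ## negative slope recovered by the robust fit
  accNeg <- simulateBehavior(NULL, iapZ, seed = 5, slope = -0.664,
                             noiseSd = 0.05)
  rf <- robustFit(iapZ, qlogis(accNeg), removeOutliers = FALSE)
  expect_equal(rf@beta1, -0.664, tolerance = 0.1)
})
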