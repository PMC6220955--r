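# alphakit

Simulation and analysis of parieto-occipital alpha dynamics under
quasi-periodic visual stimulation.

## What this package is for

A central question in visual neuroscience is whether rhythmic visual
input *entrains* the brain's intrinsic alpha rhythm (8–12 Hz): does a
flickering stimulus capture the phase of parieto-occipital alpha
generators and pull their frequency toward its own? For strictly
periodic, high-contrast flicker there is evidence that it can; for the
quasi-periodic, low-intensity contrast modulations that resemble natural
visual input, the question requires a full analysis chain — and, for a
credible null result, a demonstration that the chain would detect
entrainment if it were there.

alphakit provides that chain end to end, exercised on synthetic data:

* **Stimulus synthesis** — band-limited frequency-modulation (FM)
  functions (theta 4–7, alpha 8–13, beta 14–20 Hz) whose instantaneous
  frequency wanders under a one-bandwidth-per-second rate limit, mapped
  to luminance timecourses (7.5–29.1 cd/m²), with |r| < 0.05
  decorrelation between concurrently presented stimuli and
  target/distracter event placement.
* **Synthetic EEG** — multi-channel recordings at 512 Hz with 1/f
  background, per-hemisphere alpha oscillators with individual peak
  frequency, retinotopic attention gains (contralateral suppression),
  an optional stimulus-locked frequency-following component, and an
  optional Adler-type phase coupling
  `dphi/dt = 2*pi*f_alpha + epsilon*sin(phi_stim - phi)` that switches
  entrainment on.
* **Spectral decomposition** — 1-s epochs with 0.5-s overlap, spherical
  spline scalp current densities (lambda = 1e-4), detrended
  Hann-tapered zero-padded FFTs on an exact 0.5 Hz grid, decibel
  log-power.
* **Alpha observables** — individual alpha frequency (IAF) by the
  sign-flipped second spectral gradient smoothed with an 11-point
  third-order Savitzky–Golay filter; individual alpha power (IAP,
  mean log-power in IAF ± 1 Hz); lateralization indices; a
  phase-locking-value utility.
* **Inference** — cluster-based permutation tests on sensor
  topographies (Delaunay neighbour graph, max-statistic sign-flip
  null), Greenhouse–Geisser corrected repeated-measures ANOVA with
  partial omega squared, JZS mixture-of-g Bayes-factor ANOVA
  (r = 0.5, subject random), robust bisquare regressions with
  Cook's-distance screening and BCa bootstrap confidence intervals,
  Bonferroni-adjusted slope-difference tests, Friedman tests,
  Holm–Bonferroni correction, logit-transformed accuracies.

## Worked example

A complete synthetic study — cohort, stimuli, EEG, spectra, statistics —
runs from one configuration object:

```r
library(alphakit)
cfg <- studyConfig(nSubjects = 12, nChannels = 32, trialsPerCondition = 10,
                   periDuration = 24, nPerm = 500, nBoot = 1000,
                   nMc = 2e4, seed = 42)
rep <- runStudy(cfg)
rep
```

```
Cluster test:
ClusterTestResult: 6 cluster(s), 500 permutations, mean degree 5.4
  id sign nChannels        stat           p
2  2    1        10  102.851505 0.003992016
5  5   -1        10 -106.056988 0.003992016
...
Repeated-measures ANOVA (n = 12):
     effect     dfEff dfErr       F        p  omegaP2
 position       1    11   295.379 2.70e-09    0.958
 frequency      2    22     2.307 1.23e-01    0.095
...
JZS Bayes-factor ANOVA (r = 0.5 fixed, 1 random, 20000 MC iterations):
       term      bf10      bf01
   position 5.222e+42 1.915e-43
  frequency 1.334e-01 7.494e+00
...
Friedman on |IAF - 10.5 Hz|: chi2 = 0 , df = 3 , p = 1
```

The run reproduces the canonical null pattern: attention lateralizes
alpha power retinotopically (two opposite-sign parieto-occipital
clusters, both p = 0.004, the permutation floor at N = 500; a position
effect of F(1,11) = 295, partial omega squared 0.958, BF10 ≈ 5e42),
while the *frequency* of stimulation leaves alpha power untouched
(F(2,22) = 2.3, p = 0.12; BF01 = 7.5 — substantial evidence for the
null) and IAF distances from the 10.5 Hz alpha-stimulation centre are
identical across conditions (Friedman chi-square = 0, p = 1). The
during-on-peri IAF regression slopes are exactly 1 here because at this
signal-to-noise the 0.5 Hz-grid IAF estimates recover each subject's
true peak without error.

Switching the counterfactual on — `entrainCoupling = c(theta = 0,
alpha = 5 * pi, beta = 0)` — pulls the measured alpha-condition IAF
toward 10.5 Hz; `iafPullStatistic(rep)` quantifies the pull (about
+0.6 to +1 Hz per detuned subject in this regime, versus ~0 under the
null generator).

Individual stages are exported too:

```r
band <- stimulusBand("alpha")                  # 8-13 Hz preset
pair <- generateDecorrelatedPair(band, seed = 1)
pair$r                                         # |r| < 0.05
#> [1] 0.0267861
m    <- makeMontage(32)
subj <- subjectParams(iafTrue = 9.5, alphaAmp = 4)
rec  <- simulatePeri(subj, duration = 24, montage = m, seed = 1)
ps   <- powerSpectrum(scalpCurrentDensity(epochData(rec)))
detectIAF(ps, channels = c(leftCluster(m), rightCluster(m)))
#> [1] 9.5
```

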