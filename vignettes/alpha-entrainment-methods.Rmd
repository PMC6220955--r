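---
title: "Testing alpha entrainment by quasi-periodic visual stimulation: models and methods"
author: "alphakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing alpha entrainment by quasi-periodic visual stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphakit)
```

## The scientific question

The parieto-occipital alpha rhythm (8–12 Hz) is the dominant oscillation
of the resting human EEG, and its power and phase have repeatedly been
linked to visual perception: alpha power over each hemisphere drops when
attention is directed to the contralateral visual hemifield, and alpha
phase is thought to index periodic fluctuations of cortical excitability.
A self-sustained oscillator driven by a periodic external input can, in
principle, *entrain*: its phase locks to the drive and its frequency is
pulled toward the drive's frequency. Whether low-intensity,
*quasi-periodic* visual flicker — contrast modulations whose instantaneous
rate wanders inside a band instead of ticking at a fixed rate — entrains
intrinsic alpha generators is an open question with direct consequences
for theories of rhythmic visual sampling of natural input.

alphakit implements, end to end, the analysis chain used to answer that
question: synthesis of band-limited quasi-periodic stimulation,
a synthetic multi-channel EEG generator with controllable alpha
parameters, spectral decomposition on scalp current densities, extraction
of individual alpha observables, and the frequentist plus Bayesian
inference battery. Because the generator can simulate both the null
regime (no entrainment) and the counterfactual (an explicit phase
coupling), the package can demonstrate that the analysis chain *would*
detect entrainment were it present — the key epistemic step behind a
null result.

## Stimulus model

Each trial presents two peripheral patches whose peak luminance is
modulated sinusoidally between 7.5 and 29.1 cd/m² on a 6.5 cd/m²
background at a 100 frames/s refresh. The instantaneous modulation
frequency follows a *frequency-modulation (FM) function*: a random
trajectory confined to the condition's band — theta 4–7 Hz, alpha
8–13 Hz, beta 14–20 Hz — whose rate of change is limited to one
bandwidth per second (so ~3 Hz/s for theta). The two patches of a trial
are decorrelated: candidate FM pairs are rejection-sampled until the
Pearson correlation of their frequency traces satisfies |r| < 0.05.

The FM construction itself is under-determined by those constraints; the
package draws uniform knots on the band at 1-s spacing, interpolates
with a shape-preserving (Fritsch–Carlson) monotone cubic, and projects
onto the rate constraint with a forward clamp. This yields smooth,
meandering trajectories that satisfy every stated constraint exactly;
the projection step almost never activates in practice because the
knot-to-knot secant slope can never exceed one bandwidth per second.
The luminance timecourse integrates the FM function to a phase (with 8×
oversampling before decimation, so that phase integration does not alias
near 20 Hz) and maps it through a sinusoid. Initial phases are uniform
per stimulus per trial. Transient target/distracter events (0.3 s) occur
in one third of trials, at most twice per trial, at least 0.8 s apart.

`validateStimulus()` re-checks every constraint on a generated trial and
is used by the tests to certify thousands of seeded generations.

## EEG generator

The generator is acknowledged plumbing: nothing in the analysis assumes
its specific form, and it is validated purely through recovery
properties. Each subject carries a ground-truth parameter set
(`subjectParams()`): an intrinsic alpha frequency `iafTrue` drawn from a
truncated normal (mean 10.2 Hz, sd 0.9, bounds 8–13) across the default
17-subject cohort, an oscillator amplitude, an attention modulation in
dB, a 1/f noise exponent and amplitude, a frequency-following drive
amplitude, and an Adler coupling strength.

The signal at each channel is a Gaussian-kernel projection (on the unit
sphere) of two parieto-occipital sources plus spatially independent and
common-mode 1/f noise. Each source is an amplitude-modulated sinusoid:
a slow (≤1 Hz) positive envelope times `sin(phi(t))` with
`dphi/dt = 2*pi*iafTrue`. During stimulation the attended-side contrast
phase `phi_stim` can act on the oscillator through the Adler equation

    dphi/dt = 2*pi*iafTrue + epsilon * sin(phi_stim - phi),

the canonical reduction of a driven self-sustained oscillator. With
`epsilon = 0` the generator is the null regime. Attention scales the two
sources asymmetrically: the source contralateral to the attended side is
attenuated by `attnModulation` dB of power and the ipsilateral source
enhanced symmetrically, which reproduces the classic retinotopic
lateralization. A frequency-following response of amplitude `driveSnr`
tracks the attended stimulus phase.

Two defaults deserve justification:

* `driveSnr = 0.2` (relative to alpha amplitudes around 4). The regime
  being modelled is one where stimulus phase-locking is measurable in a
  dedicated phase-locking analysis while power spectra remain dominated
  by intrinsic alpha, with no visible bump at the stimulated band. At
  0.2 the frequency-following contribution to 8–12 Hz cluster power is
  of the order of 0.05 dB — far below the within-subject noise — while
  the phase-locking value against the stimulus remains clearly above its
  noise floor. A markedly stronger drive would add condition-specific
  band power and turn the stimulation-frequency factor non-null by
  construction, which is not the regime under study.
* `epsilon = 2*pi*2.5` rad/s for the entrainment counterfactual. The
  Arnold-tongue locking range of the Adler equation is
  `|detuning| <= epsilon/(2*pi)` Hz; 2.5 Hz matches the half-width of
  the 8–13 Hz stimulation band, i.e. the weakest coupling for which
  every stimulus frequency inside the band can in principle capture an
  oscillator detuned by up to the cohort's typical offset. Under a
  *wandering* drive full locking replaces the sharp alpha peak by the
  drive's broad spectrum, so stronger couplings paradoxically make the
  peak-based IAF estimate noisier rather than more centred.

### What the generator does not emulate

Volume conduction beyond Gaussian spatial kernels, eye and muscle
artifacts, artifact-correction pipelines, non-sinusoidal alpha
waveforms, multiple alpha sub-generators, and any systematic coupling
between behaviour and lateralization. Passing tests therefore certify
the *analysis chain* — its calibration, sensitivity and null behaviour —
not the realism of any particular biophysical assumption.

## Spectral decomposition

During-stimulation analysis windows cover 0.5–3.5 s after stimulation
onset (avoiding onset-evoked activity and the offset), cut into 1-s
epochs with 0.5-s overlap — five epochs per trial; trials containing
transient events are excluded. Peri-stimulation (rest) recordings are
segmented the same way. Epochs are converted to scalp current densities
by the spherical-spline surface Laplacian (spline order m = 4,
regularization lambda = 1e-4, 20 Legendre terms; order and truncation
are conventional defaults for the method; the regularization is the
standard choice for this paradigm). Each epoch is detrended (mean and linear trend), Hann
tapered, zero-padded to 2 s equivalent — giving exactly 0.5 Hz
resolution at 512 Hz — and squared-magnitude Fourier transformed. Power
is averaged across epochs on the raw scale and only then converted to
decibels (10·log10); the alternative order (dB first) is not
commutative with averaging, and averaging raw power is the variance-
reducing choice for a power estimate.

## Alpha observables

The individual alpha frequency (IAF) is estimated from raw cluster-mean
spectra by taking the second numerical gradient, flipping its sign and
smoothing with an 11-point third-order Savitzky–Golay filter; the IAF is
the frequency of the highest positive interior local maximum. The
curvature transform accentuates indistinct peaks riding on the 1/f
background while agreeing with the naive spectral argmax whenever a
clear peak exists (a property the test suite asserts). Choices the
method's description leaves open, fixed here once: the search window is
6–14 Hz, ties break toward the lower frequency, the filter is applied
without padding so the outermost five grid points are excluded, and
subjects without any positive curvature maximum are reported as "no
peak" and excluded listwise with a logged count.

Individual alpha power (IAP) is the mean log-power over the five grid
points in IAF ± 1 Hz. The lateralization index is contralateral-minus-
ipsilateral cluster IAP, negative under contralateral suppression. A
phase-locking value utility (band-pass, analytic-signal phase, mean
across-epoch phasor magnitude) is provided as plumbing for
stimulus-locking checks.

## Inference battery

* **Cluster-based permutation test** on paired sensor topographies:
  channel neighbours from a Delaunay triangulation of the azimuthal
  planar projection, channel threshold at two-tailed 0.05 (the
  conventional default for the method),
  cluster statistic = sum of paired t values, null distribution of the
  most extreme cluster statistic under within-subject sign flips
  (1000 permutations), doubling for two-sided correction.
* **Repeated-measures ANOVA** (hemisphere × attended position ×
  stimulation frequency) from orthonormal contrast scores, with
  Greenhouse–Geisser epsilon estimated from the contrast-score
  covariance, and effect sizes as partial omega squared,
  `df_eff(F−1) / (df_eff(F−1) + df_eff + df_err + 1)`, the partial-omega
  convention for fully within-subject designs.
* **JZS Bayes-factor ANOVA** with the subject as a random factor:
  independent mixture-of-g priors (inverse-gamma(1/2, r²/2) on g, i.e.
  Cauchy(r) on standardized effects) with r = 0.5 for fixed effects and
  r = 1 for the subject factor. In a balanced design the design-column
  groups are mutually orthogonal, so the conditional marginal likelihood
  factorizes over the eigenvalues of each group's Gram matrix and the
  Monte-Carlo integration over g (default 1e5 iterations) is fully
  vectorized; the proportional MC error is reported, and the test suite
  cross-checks the estimates against deterministic nested quadrature of
  the same integrals. Main effects are compared against the subject-only
  null, interactions against the model holding their constituent mains.
* **Robust regressions** of during-stimulation on peri-stimulation
  measures: bisquare IRLS (tuning 4.685) with the robust scale taken
  from the largest n−2 absolute residuals — uncentred, so residual ties
  produced by grid-valued IAFs cannot collapse the scale — preceded by
  Cook's-distance screening (cutoff 4/n, the common rule of thumb). IAF is
  z-scored before regression (its intercept is not interpretable); IAP
  is regressed on the raw dB scale (its intercept indexes a general
  power change). Confidence intervals are BCa bootstrap (default 10000
  resamples; 1000 is accepted via configuration), and
  pairwise slope differences are tested at the Bonferroni-adjusted level
  1 − 0.05/3, rejecting when the CI excludes zero.
* **Friedman test** on |IAF − 10.5 Hz| distances across the three
  stimulation conditions and the peri measurement (df = k − 1 = 3).
* **Behaviour**: accuracies are logit transformed (clipped at 1/(2n))
  and regressed on z-scored IAP per condition, with Holm–Bonferroni
  correction wherever families of contrasts are tested.

## The full pipeline and its two regimes

`runStudy()` wires the stages together: cohort → stimuli → EEG →
epochs → SCD → spectra → topographies → cluster test → functional
cluster definition → alpha profiles → ANOVA/BF/contrasts →
regressions → Friedman → behaviour, deterministically from the
configuration's seed. Analysis clusters are taken from the
cluster-test result when two significant clusters emerge (assigned left
and right by their mean lateral position) and fall back to the
montage-defined parieto-occipital clusters otherwise; functionally
defined clusters follow standard practice in this literature but can be
mildly asymmetric, which is why a hemisphere main effect may appear in
small montages.

With `entrainCoupling = 0` everywhere, the during-stimulation alpha
parameters equal the peri-stimulation parameters by construction, so the
pipeline must reproduce the null pattern: a strong attended-position
effect, no stimulation-frequency effect (and a Bayes factor favouring
the null), IAF regressions with slopes statistically indistinguishable
from one, and equal IAF-distance distributions. With coupling switched
on only in the alpha condition, the pipeline must detect the
counterfactual.

Detecting the IAF pull deserves care. Under a wandering drive, fully
locked oscillators lose their sharp spectral peak; the curvature-based
IAF then scatters across the stimulation band rather than landing
exactly on 10.5 Hz, and subjects whose intrinsic frequency already sits
near the centre have no room to move. `iafPullStatistic()` therefore
averages the *signed movement toward the centre*,
`sign(10.5 − IAF_peri) · (IAF_alpha − IAF_peri)`, over subjects detuned
by at least one grid step (0.5 Hz), and subtracts the same statistic
for the beta condition as a within-replicate control carrying the same
estimation noise. Under the null generator this difference is zero to
within a fraction of a grid step; under alpha-only coupling it is
positive by half a grid step or more. The acceptance suite counts a
replicate as "pull detected" when the statistic reaches 0.2 Hz.

## Problem sizes used by the automated checks

The statistical guarantees are checked at sizes chosen to give stable
Monte-Carlo estimates while keeping a full run of the suite practical on
a single CPU: 1000 trials per band for the stimulus-constraint suite,
200 synthetic spectra for IAF recovery, 500 replicates each for the
cluster-test type-I error and the BCa coverage, and full-pipeline
replicates (100 for the null pattern, 60 for the entrainment
counterfactual) at a reduced scale — 10 subjects, 16 channels, 4 trials
per condition, 8 s of rest, 256 Hz sampling (the generator's documented
minimum; the 0.5 Hz spectral grid is preserved by the padding rule) —
that preserves every stage of the chain.
The package defaults remain at the full experimental scale (17 subjects,
48 trials per condition, 96 s of rest, 10000 bootstrap resamples, 1e5
MC iterations).

## Numerical and degenerate-input choices

Seeds propagate through a deterministic child-seed scheme, so every
stochastic routine is reproducible in isolation and end-to-end runs are
byte-identical under a fixed configuration. Permutation p-values are
bounded below by 1/(nPerm+1) and never reach zero. Zero-variance
predictors raise an error (surfaced with its stage when the pipeline
hits one); constant outcomes yield a zero slope with an undefined R².
Bootstrap resamples on which a statistic cannot be computed (e.g. a
resample with zero predictor variance from grid-valued IAFs) are
dropped; an all-degenerate bootstrap distribution is flagged rather than
silently producing a zero-width interval. Zero-bandwidth stimulus bands
produce constant FM trajectories, and a correlation is treated as zero
when either trace is constant. Negative partial-omega estimates are
truncated to zero and flagged.

## Known limitations

The forward model supports cluster-level topography, not source
localization; channel counts below ~16 make the Delaunay neighbour
graph coarse and the functional cluster definition unstable. The IAF
estimator inherits the 0.5 Hz grid; effects smaller than half a grid
step are invisible to it. The Bayes-factor model assumes a balanced
complete design. The behavioural model is a one-parameter logit link
per condition and makes no attempt at psychometric realism.
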