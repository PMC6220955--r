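Package: alphakit
Title: Simulation and Analysis of Parieto-Occipital Alpha Dynamics under
    Quasi-Periodic Visual Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to synthesize quasi-periodic band-limited visual
    stimulation (frequency-modulation and contrast-modulation functions),
    simulate multi-channel EEG with controllable individual alpha
    parameters, retinotopic attention lateralization and optional
    stimulus entrainment, and analyse the result with the full spectral
    and inferential battery used in alpha-entrainment research: scalp
    current densities, Hann-tapered zero-padded spectra on a 0.5 Hz grid,
    Savitzky-Golay based individual alpha frequency detection,
    cluster-based permutation tests on sensor topographies,
    Greenhouse-Geisser corrected repeated-measures ANOVA with partial
    omega squared, JZS mixture-of-g Bayes-factor ANOVA, robust regression
    with BCa bootstrap confidence intervals, and Friedman tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    deldir,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
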