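Package: ssflicker
Title: Steady-State Flicker Analysis and Binocular Gain-Control Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the two eyes' inputs are combined in
    response to flickering light. Implements a binocular contrast
    gain-control model with interocular suppression (scalar and
    waveform modes, harmonic and intermodulation predictions),
    steady-state Fourier analysis of pupillometry and EEG trial data
    (epoching, coherent averaging, Mahalanobis outlier exclusion,
    T2circ and ANOVA2circ complex-domain statistics, bootstrap errors),
    dichoptic contrast-matching machinery (adaptive staircases,
    psychometric fits, matching contours), hierarchical Bayesian
    estimation of model parameters, and synthetic-data generators that
    emulate the full experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ssflicker-package.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'model.R'
    'spectral.R'
    'circstats.R'
    'io.R'
    'matching.R'
    'bayes.R'
    'synthetic.R'
    'pipeline.R'
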