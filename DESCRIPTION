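Package: nfalpha
Title: Frontal Alpha Asymmetry Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses a block-design EEG neurofeedback
    experiment for positive-emotion upregulation with simultaneous fMRI.
    Provides the closed-loop feedback engine (sliding-window alpha-band
    log-power asymmetry of F4 versus F3 relative to a View-block baseline,
    with bar smoothing, success colouring, and a sham generator), seeded
    synthetic data generators for EEG/ECG, ROI-level and voxel-level BOLD,
    and psychometric scores, offline EEG preprocessing and group statistics,
    block-design GLM activation analysis with permutation cluster
    correction and ROI percent signal change, blockwise Pearson functional
    connectivity with differential-network extraction under FDR control,
    heart-rate-variability summaries, and a shared statistical kernel
    (t tests, ANOVA, Kolmogorov-Smirnov normality, Benjamini-Hochberg FDR,
    pooled-SD Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
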