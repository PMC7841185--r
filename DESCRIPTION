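Package: eegstroke
Title: Quantitative EEG Biomarkers and Lesion-Volume Regression for Experimental Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-channel epidural rat EEG
    with auditory evoked responses graded by a ground-truth ischaemic lesion volume.
    Implements zero-phase Butterworth band-pass conditioning, event-locked epoching
    with baseline correction and decimation, Welch power spectral density with
    relative band powers and slow/fast ratios (DAR, DTABR), auditory evoked potential
    peak amplitude and latency extraction, nonparametric group comparisons
    (Kruskal-Wallis, pairwise Mann-Whitney with Bonferroni correction), univariate
    and all-subsets linear regression with RMSE/AIC/BIC ranking, collinearity
    diagnostics, SPSS-style stepwise selection, and repeated random-split validation
    with feature-selection frequencies. A synthetic-cohort generator with known
    ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
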