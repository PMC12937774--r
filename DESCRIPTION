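Package: gvscreen
Title: EEG-Biomarker Screening of Galvanic Vestibular Stimulation Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ranking large libraries of galvanic vestibular
    stimulation (GVS) waveforms by their immediate effect on resting-state
    EEG in Parkinson's disease. Implements a 304-stimulus waveform library
    with 37 morphology categories, a seeded synthetic EEG cohort generator
    with planted patient-versus-control biomarker contrasts, 16 spectral,
    burst, waveform-shape, aperiodic and complexity biomarkers computed on
    standardized 2 s windows, a leave-one-subject-out LASSO composite score,
    TOPSIS-based stimulus evaluation scores, and category-level inference
    (Kendall's W concordance, one-tailed Wilcoxon rank-sum tests with
    Benjamini-Hochberg correction, per-channel paired-t interval maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
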