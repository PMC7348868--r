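Package: pseudovoice
Title: Acoustic Feature Pipeline for Depression-versus-Dementia Speech Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screening pseudodementia (depression-driven
    cognitive impairment) against true dementia from clinical interview speech.
    Provides a seeded source-filter synthetic cohort generator, waveform
    preprocessing (inter-quartile-range outlier interpolation by cubic
    smoothing spline, amplitude normalization, edge-silence trimming),
    extraction of 108 session-level acoustic features (pitch, harmonics-to-noise
    ratio, zero-crossing rate, 14 mel-frequency and 14 gammatone cepstral
    coefficients, spectral moments) on 10 ms windows, cohort filtering by
    clinical inclusion criteria, correlation and Bonferroni-corrected t-test
    statistics, LASSO-vote feature selection inside nested 10-fold
    cross-validated support vector machines, and confusion-matrix agreement
    metrics (Cohen's kappa, Matthews correlation).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    caret,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
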