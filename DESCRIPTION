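Package: eegmse
Title: Multiscale-Entropy EEG Complexity Analysis with Penalized
    Logistic Regression and Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying dementia-related changes in EEG signal
    complexity. Computes multiscale entropy (coarse-graining plus sample
    entropy) on multichannel resting EEG, classifies severity groups with
    natively implemented LASSO and elastic-net logistic regression under
    leave-one-subject-out cross-validation, summarises per-fold feature
    selections as topographic selection-frequency maps on the 10-20
    montage, and relates complexity features to neuropsychiatric symptom
    scores through canonical correlation analysis with structure
    coefficients. Includes a seeded synthetic cohort generator (white/pink
    noise mixtures plus a linear-Gaussian symptom model) so the whole
    pipeline is testable without clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
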