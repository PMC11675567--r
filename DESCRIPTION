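Package: voicecog
Title: Voice-Based Cognitive-Status Screening Pipeline
Version: 0.1.0
Authors@R:
    person("Voicecog", "Developers", email = "voicecog@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cognitive status from sustained-vowel and
    diadochokinetic (DDK) speech recordings. Provides a source-filter
    synthetic-voice generator with controllable jitter, shimmer, noise and
    formants; extraction of 23 acoustic features per task (jitter and
    shimmer families, harmonics-to-noise ratio, fundamental-frequency and
    formant statistics, duration) giving 184 indicators over 8 tasks;
    K-MMSE-based cohort grouping with nonparametric demographic tests;
    three binary classification experiments over four model families with
    precision-recall AUC evaluated against the prevalence baseline; and
    Shapley-value feature attribution with an exact enumeration oracle and
    a seeded permutation-sampling estimator. A command-line workflow runs
    the whole study end to end from a single config file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    jsonlite,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
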