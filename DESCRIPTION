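Package: flemark
Title: Multimodal Neurocognitive Markers of Frontal Lobe Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating multimodal markers of frontal
    lobe epilepsy (FLE): a copula-based weighted Symbolic Dependence Metric
    (wSDM) for resting-state functional connectivity, scoring and mixed-design
    analysis of naturalistic text-comprehension questionnaires, tract-level
    fractional-anisotropy group comparisons with permutation-based family-wise
    error control, an FDR-corrected brain-behavior correlation screen, and
    Bayesian-tuned gradient-boosting classification with feature importance
    and ablation analyses. A synthetic-cohort generator with planted effect
    structure makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    xgboost,
    pROC,
    lhs,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
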