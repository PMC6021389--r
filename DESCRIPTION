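Package: adbn
Title: Bayesian Network Modelling of Alzheimer's Disease Severity from
    Heterogeneous Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid pipeline for multi-class Alzheimer's disease severity
    classification from heterogeneous tabular cohort data, using the Clinical
    Dementia Rating (CDR) as the severity index.  Implements supervised CAIM
    (class-attribute interdependence maximization) discretization,
    entropy-based feature selection (information gain, gain ratio, symmetrical
    uncertainty) under k-fold cross-validation, SMOTE class balancing,
    constrained hill-climbing structure learning of discrete Bayesian networks
    under K2/BDe/mBDe/BIC scores, exact inference by variable elimination, and
    hold-out evaluation (multi-class accuracy with Clopper-Pearson intervals,
    macro one-vs-rest AUC, per-class sensitivity/specificity).  Ships a
    synthetic longitudinal cohort generator with a known ground-truth network
    so that every stage is testable without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
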