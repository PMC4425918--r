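Package: dynjm
Title: Joint Models and Dynamic Event Prediction for Longitudinal Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood joint models linking a linear mixed-effects
    submodel for a longitudinal biomarker (natural-log scale) to
    relative-risk survival submodels through the current value of the
    subject-specific trajectory.  Provides subject-specific dynamic
    event-free probability curves that update as new biomarker measurements
    accrue, time-dependent ROC/AUC discrimination with subject-level
    bootstrap internal validation, and a cohort simulator with
    trajectory-linked hazards for end-to-end testing of the full analysis
    pipeline.  Motivated by serial brain natriuretic peptide (BNP)
    monitoring of patients with severe aortic stenosis, where both death
    and aortic-valve intervention are outcomes of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    nlme,
    survival,
    jsonlite,
    yaml,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
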