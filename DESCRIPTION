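Package: phishdyn
Title: Decision Dynamics and Hierarchical Bayesian Models for Phishing
    Threat Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mouse-tracking studies of phishing threat
    detection. Normalizes mouse trajectories to a canonical unit frame and
    computes three real-time decision-dynamics measures (signed area under
    the curve, multiscale sample entropy with an autocorrelation-based
    Theiler window, and response time), scores security-knowledge and
    website-familiarity surveys, fits nested hierarchical Bayesian logistic
    regression models of detection accuracy with Student-t priors and
    partially pooled participant intercepts, and compares models by
    10-fold cross-validated expected log pointwise predictive density and
    posterior-predictive accuracy. Includes a seeded synthetic-data
    generator that emulates the statistical structure the models assume, so
    the full pipeline is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
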