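Package: trajlmm
Title: Multilevel Growth-Curve Trajectory Analysis for Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trajectory (growth-curve) analysis of repeated-measures
    data: wide-to-long reshaping with validation, polynomial linear mixed
    models with random intercepts and slopes fitted by maximum likelihood or
    restricted maximum likelihood, delta-method predictions and confidence
    intervals at arbitrary ages, analytic area-under-the-curve inference,
    between-group trajectory contrasts, individual-level (BLUP) trajectories,
    plain-language summary reports, and a synthetic longitudinal cohort
    generator for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
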