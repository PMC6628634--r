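Package: mdmcpt
Title: Cumulative Prospect Theory Modeling of Risky Choice on the MDM Gamble Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling risky decision-making on the Michigan
    Decision-Making (MDM) two-gamble task with cumulative prospect theory
    (CPT). Provides a structured generator and validator for the 126-trial
    task, the CPT value and two-parameter probability-weighting functions
    with a logistic choice rule, a synthetic-cohort simulator with
    group-level parameter heterogeneity and clinical covariates, per-subject
    maximum-likelihood estimation of the four CPT parameters (value
    discrimination, loss aversion, weighting curvature and elevation) with a
    penalized hierarchical alternative, and the downstream group statistics:
    Bonferroni-corrected group comparisons, one-sample loss-aversion tests,
    expected-value optimality (Delta-EV) analysis with mixed ANOVA, and
    parameter-clinical correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
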