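Package: dynrisk
Title: Dynamic Landmark Risk Monitoring with Cox Supermodels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dynamic prediction of time-to-event outcomes by
    landmarking. Simulates longitudinal cohorts with time-varying
    covariates, acute trigger events, desistance (risk decay with
    event-free time) and competing censoring; builds sliding-window
    landmark supersets with acute/short-term/residual trigger encodings;
    fits Cox proportional-hazards supermodels with landmark-specific
    Breslow baseline hazards (dynamic, fixed-covariate landmark, and
    fixed-baseline variants); handles missing covariates by
    expectation-maximisation multiple imputation with Rubin's-rules
    pooling and AIC-equivalent backward elimination; and validates models
    dynamically with optimism-corrected concordance, time-varying AUC,
    Brier and Brier skill scores, decile calibration and threshold
    classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
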