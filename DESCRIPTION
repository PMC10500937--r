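Package: losrank
Title: Risk-Adjusted ICU Length-of-Stay Quality Metrics and Rank Confidence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for profiling intensive care units (ICUs) by
    length of stay (LOS). Simulates patient-level ICU registries with a
    calibrated right-skewed LOS distribution and known site effects;
    fits the two standard estimators (a linear mixed model on log LOS
    and a gaussian-family log-link generalised linear mixed model on
    raw LOS, each with an ICU random intercept); computes per-ICU
    quality metrics (observed-minus-expected LOS, arithmetic and
    geometric risk-adjusted LOS ratios, site random effects) with
    bias-corrected and accelerated bootstrap intervals; constructs
    marginal and simultaneous confidence sets for ICU ranks; and
    quantifies the concordance of rankings across models and metrics.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    lme4,
    glmmTMB,
    ggplot2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    boot,
    minpack.lm,
    jsonlite,
    knitr
Config/testthat/edition: 3
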