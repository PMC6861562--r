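Package: agebias
Title: Bias Adjustment for Brain-Age Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating brain age from regional neuroimaging
    features and correcting the age-dependent bias (regression dilution)
    that afflicts brain-age deltas. Implements an offset correction based
    on regressing delta on chronological age, the rescaling correction of
    Cole and colleagues, and a covariate-adjusted (ANCOVA) group
    comparison, together with a cross-validated estimation harness, a
    full statistical evaluation protocol (MAE, RMSE, affine-invariant
    R-squared, bootstrap model comparison, Levene variance tests, ANOVA
    with Tukey HSD, Cohen's d), and a synthetic cohort generator that
    reproduces the attenuation geometry of noisy feature-based age
    prediction so the whole pipeline is testable without access-controlled
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    e1071,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
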