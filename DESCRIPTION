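Package: operant
Title: Touchscreen Operant Behaviour Analysis and Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-level touchscreen operant data:
    progressive-ratio breakpoints, within-session response-rate decay
    fitting (peak rate and decay rate by nonlinear least squares),
    extinction phase analysis, visual discrimination/reversal
    perseveration metrics, and normality-gated two-group comparisons.
    Includes a seeded stochastic agent simulator that generates synthetic
    cohorts with genotype presets, so every analysis stage can be
    validated by parameter recovery without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
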