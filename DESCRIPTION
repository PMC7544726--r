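Package: radshare
Title: Assigned Share of Radiation in Cancer Causation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the assigned share (probability of causation) of past
    radiation exposure for a diagnosed cancer, with full Monte Carlo
    uncertainty propagation. Implements generic excess relative risk (ERR)
    and excess absolute rate (EAR) models with multivariate-normal parameter
    sampling, S-shaped latency adjustment, a dose-rate effectiveness factor
    (DREF) with dose-rate-dependent spread, mixed additive/multiplicative
    risk transfer between populations, multi-model inference with Akaike
    weights, linear 'twin' models for non-linear dose responses, and a
    Poisson-regression fitter for grouped person-year cohort tables.
    Includes a synthetic-data module so the whole toolchain is testable
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
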