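Package: myxindic
Title: Effort-Aware Substrate Affinities and Indicator Analysis for Slime
    Mould Occurrence Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for effort-aware analysis of substrate affinities in
    occurrence archives of slime moulds (Eumycetozoa) and similar
    presence-only biodiversity data. Ingests Darwin-Core-style occurrence
    tables, harmonises verbatim microhabitat descriptors to a consolidated
    ten-class substrate vocabulary, and aggregates records to country by
    substrate by species count frames with leave-one-out effort offsets.
    Provides Good's coverage, Hill-number rarefaction and coverage-based
    standardisation with bootstrap intervals; zero-truncated
    negative-binomial mixed models of per-unit-effort recording intensity
    with estimated-marginal-mean contrasts, bootstrap rank uncertainty and
    order-level random-slope deviations; effort-weighted indicator-value
    (IndVal) analysis with country-blocked permutation tests,
    Benjamini-Hochberg adjustment, stratified bootstrap intervals and
    blocked K-fold held-out validation; effort-adjusted Poisson-spline
    elevational profiles with bootstrapped modal elevations; and a
    validation suite covering randomized-quantile residual diagnostics,
    leave-one-country-out cross-validated calibration, sensitivity model
    variants and pH-mode resolution concordance. A synthetic archive
    generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    purrr,
    rlang,
    sandwich,
    splines,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
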