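Package: hfpartition
Title: Partitioning Trends in Disease Prevalence and Incidence-Based Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing time trends of chronic-disease prevalence and
    incidence-based mortality (IBM) into contributions from pre-existing
    prevalence, disease incidence, post-diagnosis survival, and general-population
    mortality, as used in claims-based studies of heart failure among older
    adults. Includes a synthetic Medicare-like beneficiary and claims simulator
    with known ground truth, claims-based case ascertainment (two-claim
    confirmation), person-year aggregation, age-standardized rate and
    Kaplan-Meier/relative survival estimation, spline trend smoothing, an exact
    additive partition of logarithmic derivatives with phase classification, and
    an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tools,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
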