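Package: clabsitools
Title: Rule-Based CLABSI Risk Scoring and Surveillance Metrics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for surveillance of central-line-associated
    bloodstream infections (CLABSI). Implements a categorical rule engine that
    scores patient line-list records against a 24-predictor risk catalog,
    classifies each record into four color-coded risk categories by a
    threshold rule, and summarises cohorts as prediction reports. Includes a
    seeded simulator that generates synthetic patient records constrained to
    the catalog with clinical interdependency rules, line-list CSV/JSON input
    and output with validation, and hospital surveillance metrics: device
    utilization ratio (central-line days over patient days) and standardized
    infection ratio (observed over predicted cases) with period averages and
    reduction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
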