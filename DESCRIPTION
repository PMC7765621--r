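Package: srssignal
Title: Signal Detection and Risk-Factor Modelling for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance analysis of
    spontaneous adverse-event reporting databases in the JADER (Japanese
    Adverse Drug Event Report) layout: reading and cleaning of DRUG/REAC/DEMO
    case tables, reporting-odds-ratio (ROR) disproportionality analysis with
    the Haldane-Anscombe half correction and Fisher's exact test, volcano-plot
    signal detection, multivariate logistic risk-factor modelling with unit
    and range odds ratios, and drug-by-event ln(ROR) profiling via
    correlation-matrix PCA and Ward hierarchical clustering. Includes a
    seeded synthetic report generator with designed drug-event association
    strengths so every stage is testable without the external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
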