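Package: sccspipe
Title: Self-Controlled Case Series Analysis with Pre-Exposure Risk Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for self-controlled case series (SCCS)
    analysis of medication safety from routinely collected prescription and
    diagnosis records. Converts prescriptions into exposure episodes, constructs
    per-patient observation windows under study entry/exit and censoring rules,
    partitions person-time into intervals homogeneous in exposure category, age
    band and season, and fits the conditional Poisson (multinomial) likelihood
    by Newton-Raphson to estimate incidence rate ratios with Wald confidence
    intervals. Includes a pre-exposure (reverse-causality) risk window, a
    declarative battery of sensitivity scenarios, analytic SCCS sample-size and
    power calculations, and a seeded synthetic-cohort simulator with a
    piecewise-constant hazard so every stage is testable without access to
    confidential source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
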