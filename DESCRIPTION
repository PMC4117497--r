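Package: stemipathway
Title: Care-Pathway Delay Analysis for STEMI Transfer Hospitals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of treatment delays for ST-elevation
    myocardial infarction (STEMI) patients presenting at hospitals without
    catheterization capability. Provides a calibrated synthetic-cohort
    generator for the four sequential care stages (first medical contact,
    ECG acquisition, ECG transmission and feedback, transfer wait), a
    crisp-set Qualitative Comparative Analysis (csQCA) engine with
    Quine-McCluskey Boolean minimization and necessity/sufficiency fit
    measures, a continuous-time stock-and-flow (aging chain) simulator of
    the pathway with improvement policies, and Monte-Carlo sensitivity
    analysis producing percentile envelopes over policy uncertainty.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
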