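Package: emrdq
Title: Data Quality Assessment for Primary Care EMR Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A basic model for assessing the quality of primary health care
    electronic medical record (EMR) data. Implements eleven operationalized
    measures in four domains (comparability, completeness, correctness,
    currency) over a relational EMR extract: age-sex structure versus a
    standard population, crude and directly age-standardized prevalence with
    gamma confidence intervals, sensitivity and positive predictive value of
    billing codes against rule-based case definitions, consistency of capture,
    vitals recording and timeliness windows, and an unlikely age-by-procedure
    check. Ships a declarative case-definition engine for six test conditions
    (diabetes, hypertension, hypothyroidism, asthma, obesity, urinary tract
    infection) and a synthetic EMR generator with a ground-truth ledger so the
    whole pipeline can be exercised without real patient data.
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
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
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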