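Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event reports: reading the quarterly
    relational tables (DEMO, DRUG, REAC, THER, OUTC) in the $-delimited
    ASCII or CSV dialects, FDA-recommended case deduplication, primary-
    suspect drug selection, MedDRA PT-to-SOC aggregation, four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio, Bayesian confidence propagation neural network
    information component, and the observed/expected EBGM with its lower
    bound) with their standard signal criteria, four-algorithm intersection
    screening, descriptive report characterization, an age-restricted
    sensitivity analysis, and time-to-onset binning. Ships a synthetic
    FAERS-like data generator with planted relative-risk signals so the
    whole pipeline is testable without access to the licensed source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
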