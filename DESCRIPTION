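Package: anticoagr
Title: Warfarin Anticoagulation Management Engines and Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative warfarin anticoagulation management:
    indication-specific INR target ranges with a five-level INR
    classification, time-in-therapeutic-range by Rosendaal linear
    interpolation, a rule-based warfarin dose-titration engine with an
    INR-triggered hold/recheck state machine, an INR monitoring-interval
    protocol, a seeded two-arm virtual-patient cohort simulator, and the
    cohort comparison layer (normality-gated group tests, contingency-table
    analysis, Kaplan-Meier time-to-first-event curves with log-rank tests,
    and two-proportion sample-size calculations with attrition inflation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
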