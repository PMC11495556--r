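Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("FAERS", "Signal Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FAERS-style
    spontaneous adverse-event report databases: ingestion of the quarterly
    dollar-delimited ASCII tables (DEMO/DRUG/REAC/THER/OUTC), case
    deduplication, primary-suspect drug filtering, MedDRA PT/SOC
    standardisation, 2x2 contingency construction and four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with Pearson chi-square, the BCPNN information
    component, and a simplified empirical Bayes geometric mean), signal
    criteria and unexpected-signal flagging, descriptive case
    characteristics, and time-to-onset summaries.  Includes a synthetic
    report generator with planted drug-event reporting-rate ratios so the
    whole pipeline is testable without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
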