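Package: fallsignal
Title: Disproportionality and Association-Rule Analysis of Fall-Related
    Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pharmacovigilance analysis pipeline for fall-related adverse
    events in a spontaneous-reporting-system database with a four-table
    JADER-like schema (demographics, drugs, reactions, patient history).
    Builds report-level 2x2 contingency tables and crude reporting odds
    ratios with Woolf 95% confidence intervals and signal criteria,
    classifies drugs into the ATC classes of the 2015 Beers Criteria
    CNS-active set, mines association rules with a level-wise apriori
    implementation scored by support, confidence, lift and a lift-based
    chi-squared statistic, and simulates synthetic reporting databases
    with planted multiplicative risk effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
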