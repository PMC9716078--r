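Package: pvsignal
Title: Disproportionality Signal Detection and Death-Risk Modelling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous
    reporting-system data in the FAERS quarterly-extract dialect: case
    parsing and deduplication, extraction of a drug cohort against a
    preferred-term event cluster, three disproportionality statistics
    (reporting odds ratio, Bayesian confidence propagation neural network
    information component, and the simplified empirical Bayes geometric
    mean) with a combined signal criterion, therapy-start-to-event onset
    summaries, co-medication adjusted odds ratios, and a logistic
    death-risk nomogram validated by ROC analysis, bootstrap calibration,
    and decision-curve analysis. A synthetic report generator with known
    ground truth (injected association strength, demographic marginals,
    onset-time law, and death-model coefficients) makes every stage
    testable without access to the full regulatory database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
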