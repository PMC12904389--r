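Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("FAERS Signal", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal mining on FDA Adverse Event
    Reporting System (FAERS) style quarterly ASCII tables: case ingestion and
    deduplication, primary-suspect cohort selection, 2x2 contingency
    construction at the MedDRA preferred-term (PT) and system-organ-class
    (SOC) levels, and four disproportionality statistics (reporting odds
    ratio, proportional reporting ratio with chi-squared, the Bayesian
    confidence propagation neural network information component, and the
    empirical Bayes geometric mean) combined into an all-four positive-signal
    rule. Includes a synthetic spontaneous-report generator with known
    ground-truth signal structure, descriptive demographic and time-to-onset
    summaries, a back-solver that recovers contingency tables from published
    statistics, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
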