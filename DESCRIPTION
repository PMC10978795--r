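Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for mining adverse drug event
    signals from spontaneous reporting databases in the FAERS quarterly
    ASCII dialect. Reads and deduplicates case reports, selects reports
    where a focal drug is the primary suspect, builds per-event 2x2
    contingency tables, and computes four disproportionality statistics
    with their decision thresholds: the reporting odds ratio (ROR), the
    MHRA criteria (proportional reporting ratio with Yates-corrected
    chi-squared), the Bayesian confidence propagation neural network
    information component (IC025), and the unshrunk empirical Bayes
    geometric mean (relative reporting ratio) with its lower bound.
    Signals are tiered by consensus across the four algorithms, rolled up
    from MedDRA preferred terms to system organ classes, and summarised
    with onset-time distributions and descriptive report tables. Includes
    a seeded synthetic spontaneous-report generator with known injected
    signals so the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
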