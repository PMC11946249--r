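Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    on FAERS-style spontaneous reporting data. Reads quarterly "$"-delimited
    ASCII extracts, assembles and deduplicates case reports, canonicalizes drug
    names, maps MedDRA Preferred Terms to System Organ Classes, consolidates
    liver-injury terms into a unified drug-induced liver injury (DILI) event,
    builds report-level 2x2 contingency tables, and computes four
    disproportionality statistics (reporting odds ratio, proportional reporting
    ratio with Pearson chi-squared, Bayesian confidence propagation IC, and the
    DuMouchel multi-item gamma Poisson shrinker EBGM) with threshold-based
    signal classification, top-k ranking, cross-drug signal overlap, and cohort
    descriptive profiles. Includes a synthetic multi-table report generator
    with known injected signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
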