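Package: studbookMLE
Title: Median Life Expectancy from Studbook Records by Left-Truncated
    Kaplan-Meier Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates sex-specific median life expectancies (MLE) with 95%
    confidence limits from individual-level ex situ population records
    (studbooks), using the left-truncated, right-censored Kaplan-Meier
    product-limit estimator with survivorship anchored at age 365 days.
    Confidence limits for the median are obtained by inverting the
    log-log-transformed Z statistic with Greenwood's variance.  Five
    data-quality tests flag strata whose MLE cannot be reliably estimated.
    Includes a studbook reader with record-level validation and exclusion
    logging, a synthetic-studbook simulator with known survival structure,
    readers and writers for a per-species MLE dataset schema with taxon
    summaries, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
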