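Package: carepathqi
Title: Automated Care-Pathway Quality Indicators from EHR Event Logs, with
    Validation Against Manual Abstraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing clinical quality indicators from routinely
    collected, structured electronic health record (EHR) data in a head and
    neck oncology care pathway, and for validating the automatically
    extracted dataset (AED) against a manually abstracted dataset (MED).
    Includes a synthetic event-log generator with configurable discrepancy
    injection (referral-date proxies, systematic one-day extraction shifts,
    weekly tumor-board selection ambiguity, inpatient-only physiotherapy
    capture, second systemic-therapy rounds), an extraction engine that
    derives patient abstracts from event logs, cohort inclusion/exclusion
    filtering, record linkage with coverage, per-variable percent agreement,
    date-difference distributions, Cohen's kappa, and a ten-indicator quality
    measurement engine with manual-versus-automatic comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
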