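Package: rippval
Title: Validation Analysis of Clinical Decision Aids for Acute Aortic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for validating points-based clinical decision
    aids for acute aortic syndrome (AAS) on case-control cohorts. Implements
    the RIPP score (risk factors, impression, physical exam, pain) and a
    declarative engine for comparator tools (ADD risk score, Lovy,
    Von Kodolitsch, AORTAs), a seeded synthetic case-control cohort generator
    calibrated to published per-arm feature prevalences, and the comparative
    diagnostic-accuracy battery: sensitivity and specificity with exact
    Clopper-Pearson confidence intervals, empirical AUC with the DeLong
    variance and paired DeLong tests of correlated AUCs, and net
    reclassification indices with full reclassification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
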