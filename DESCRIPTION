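Package: lcscreen
Title: Identify Lung Cancer Screening Exams from Radiology Order Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based identification of lung cancer screening (LCS)
    low-dose chest CT exams from radiology orders. Classifies each order as
    screening, non-screening, or unable-to-classify using CPT-code scope
    filters, encounter setting, imported-exam markers, and term matching
    over the order's procedure name and free-text fields, with
    exception-phrase masking for misleading screening language. Includes
    diagnostic-accuracy validation against chart-review gold labels
    (sensitivity, specificity, PPV, NPV with exact Clopper-Pearson
    intervals, survey-weighted variants, and two-proportion comparison
    against an administrative-code baseline), a synthetic radiology-order
    generator with configurable misclassification noise for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
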