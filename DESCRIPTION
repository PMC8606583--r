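Package: oddsrules
Title: Odds-Ratio Associative Classification for In-Hospital Mortality Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines single-item association rules of the form
    "clinical variable implies in-hospital mortality" from categorical
    electronic-health-record itemsets, using the odds ratio as the rule
    quality measure and the normal approximation of the log odds ratio
    (Woolf) as a significance filter with optional Bonferroni correction.
    Filtered rule sets form interpretable risk models that score unseen
    cases by the mean odds ratio of applying rules against a calibrated
    decision boundary. Includes a full evaluation harness (repeated
    train/test splits, ROC/AUC, Youden-index boundary selection,
    confusion metrics, rule-set summaries) and a synthetic EHR population
    generator with planted per-item odds ratios, so the whole pipeline is
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
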