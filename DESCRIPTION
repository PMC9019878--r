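Package: thyrostrat
Title: Molecular Risk Stratification of Indeterminate Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alteration-weighted classifier calling and
    diagnostic-performance analysis of molecular tests on cytologically
    indeterminate thyroid nodules (Bethesda III/IV). Provides a data model
    for molecular alterations (SNVs, indels, fusions, expression flags)
    with a common-variant population-frequency filter and risk tiers, an
    additive genomic-classifier scoring engine with configurable weights
    and positivity thresholds, a seeded synthetic-cohort simulator with
    Beta-calibrated class-conditional score distributions, estimators for
    sensitivity, specificity, predictive values, risk of malignancy and
    resection rates with Wilson or continuity-corrected Wald confidence
    intervals, chi-squared cross-study comparison, Mann-Whitney AUC, and
    prevalence-projected expected PPV/NPV curves with rule-in/rule-out
    mode recommendation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
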