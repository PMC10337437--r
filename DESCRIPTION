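Package: carecascade
Title: Fixed-Denominator Cascade-of-Care Analysis for Type 2 Diabetes Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for care-continuum ("cascade of care") analysis of type 2
    diabetes (T2D) from cross-sectional survey microdata. Classifies
    participants into cascade stages (prevalent case, ever tested, ever
    diagnosed, in care, in treatment, under glycaemic control) from fasting
    blood glucose, HbA1c and self-report, builds fixed-denominator cascades
    overall and by care-initiative setting, computes an asset-based household
    wealth index with quintiles, runs bivariate contingency tests, and fits a
    multiple logistic regression for predictors of undiagnosed T2D with
    block-wise backward elimination. Includes a synthetic survey population
    generator and a deterministic reconstruction of individual-level data
    from published aggregate counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    yaml,
    withr,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
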