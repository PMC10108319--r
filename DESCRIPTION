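Package: lnrrmiss
Title: Meta-Analysis of Log Response Ratios with Missing Standard Deviations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Effect-size and variance estimators for the log response ratio
    (lnRR) when some studies do not report standard deviations. Implements
    sample-size-weighted pooling of coefficients of variation, five strategies
    for handling missing SDs (complete-case, missing-cases, all-cases,
    multiplicative, hybrid), restricted maximum likelihood fitting of
    random-effects and multilevel meta-analytic models with an optional
    multiplicative variance-proportionality parameter, the improved Geary
    normality screen, and a simulation harness for evaluating bias, confidence
    interval coverage, and heterogeneity estimation of the strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
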