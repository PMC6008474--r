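Package: repromr
Title: Mendelian Randomisation of Reproductive Timing and Colorectal Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument curation, weighted genetic risk score construction and
    year-scaling, one-sample genetic-risk-score logistic Mendelian
    randomisation with stratified and sensitivity analyses, two-sample
    estimators (inverse-variance weighted, MR-Egger, weighted median with
    bootstrapped standard errors), instrument diagnostics (F-statistic,
    confounder screen, funnel data) and analytic/simulation power calculation
    for studies of genetically predicted age at menarche and age at menopause
    on colorectal cancer risk, together with a synthetic cohort generator
    that emulates the statistical structure of such case-control consortia.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
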