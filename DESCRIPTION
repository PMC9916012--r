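Package: igscore
Title: Intersectional Gender-Score Stratification for Health Monitoring
Version: 0.1.0
Authors@R:
    person("Kim", "Weber", email = "kim.weber@example.org",
           role = c("aut", "cre"))
Description: Tools for intersectionality-informed sex/gender-sensitive
    description of population health. Estimates an intersectional
    gender-score (the predicted probability of being recorded as a woman
    conditional on sociocultural, sociodemographic and socioeconomic
    covariables) by gradient-boosted trees or logistic regression, trims
    the sample to the region of common support, partitions it into
    equal-size score strata chosen to minimise covariable imbalance,
    quantifies balance by standardized mean differences, and compares
    prevalence of binary health indicators between men and women within
    and across sex/gender-imbalanced strata. Includes a synthetic survey
    cohort generator emulating the structure of large household panels so
    the whole pipeline is testable without access-restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
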