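Package: dietcmr
Title: Leading Dietary Determinants and a Healthy Diet Score for
    Cardiometabolic Risk in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a longitudinal analysis of diet and cardiometabolic
    risk in school-age children: aggregation of 3-day 24-hour dietary
    recalls into energy-adjusted food-group intakes (grams per 100 kcal),
    derivation of clinical measures (BMI, mean arterial pressure, HOMA-IR)
    and an age- and sex-standardized composite cardiometabolic risk score
    (CMRS), ranking of food groups by their importance for one-year change
    in CMRS using penalized regression, random forests, and gradient
    boosting, construction of unweighted and importance-weighted Healthy
    Diet Scores (HDS) from the leading determinants, and estimation of
    adjusted associations between HDS and changes in cardiometabolic
    factors under nested mixed-effects models with false discovery rate
    control. Includes a synthetic cohort generator with planted effects
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    ranger,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
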