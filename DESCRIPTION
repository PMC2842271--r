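Package: fructuric
Title: Individual Dietary Fructose Intake Estimation and Hyperuricemia Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates individual dietary fructose intake from 24-hour
    dietary recalls by decomposing foods into agricultural commodities,
    resolving per-commodity fructose content (with ratio-based imputation
    from related commodities when a direct value is missing), identifying
    added caloric sweeteners, partitioning corn sweeteners into high-fructose
    corn syrup components, and accounting separately for unbound
    (monosaccharide) and bound (sucrose-moiety) fructose. Builds an
    analysis-ready cohort with sex-specific hyperuricemia classification,
    quartile exposure coding and demographic categorization, and fits
    survey-weighted descriptive statistics, general linear models with
    Dunnett many-to-one comparisons, and logistic regression risk models
    with odds ratios, Wald confidence limits and Hosmer-Lemeshow
    goodness-of-fit. Includes a synthetic cohort generator with planted,
    known effect sizes so the whole pipeline can be validated end-to-end
    by parameter recovery without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    multcomp,
    jsonlite,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
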