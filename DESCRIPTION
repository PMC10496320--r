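Package: dietquality
Title: Diet-Quality Index Scoring and Inflammation Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies habitual dietary intake from semi-quantitative food
    frequency questionnaire (FFQ) responses using a food-composition table,
    computes six diet-quality adherence indices (DASH, a dairy-adjusted DASH
    variant, the Vegetarian Lifestyle Index, HEIFA, MEDAS and the 17-item
    energy-restricted Mediterranean screener), and fits the covariate-adjusted
    standardised-coefficient regression models relating the scores to
    inflammatory biomarkers (hsCRP, platelet-activating factor, Lp-PLA2),
    including exponentiated-coefficient back-transformation, correlation
    matrices with magnitude labels, quartile summaries and Pearson-correlation
    power analysis. A synthetic-cohort generator emulates the full study input
    set (FFQ, GPAQ physical activity, beverage diaries, covariates and
    biomarkers) with a configurable latent diet-quality effect so that the
    entire pipeline is testable without access to participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
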