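Package: upfdiet
Title: Ultra-Processed Food Energy Share Scoring and Cohort Modelling for
    Food Frequency Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts categorical food frequency questionnaire (FFQ)
    responses into grams per day and nutrient intakes, classifies foods by
    the NOVA processing scheme, recomputes dietary energy from macronutrients,
    and derives each subject's percent of energy intake from ultra-processed
    foods (PEI-UPF). Includes iterative random-forest imputation of missing
    categorical responses, ANCOVA-style regression of maternal and neonatal
    outcomes with forced and screened interactions, dietary-index comparison
    via adjusted R-squared and extra sum-of-squares F-tests, residual
    diagnostics, and a synthetic cohort generator that reproduces the
    statistical structure the models assume so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
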