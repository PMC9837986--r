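Package: ffqscore
Title: Nutrient Scoring, Energy Adjustment and Reliability Analysis for
    Food-Frequency Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A questionnaire-agnostic engine that converts self-reported
    food-frequency answers into per-day intake of energy and sixteen
    nutrients (including dietary fiber and its subclasses). Implements the
    53-item DEGS1-style scoring pipeline: mean daily portions from
    frequency and portion categories, resolution of 'type' follow-up
    questions against a per-100 g food composition reference table,
    per-day nutrient totals, interquartile-range energy outlier filtering,
    and energy adjustment of nutrients by the Willett residual method.
    Ships reliability statistics (Pearson correlation, ICC(2,1) two-way
    random single-measure absolute agreement with F-based confidence
    intervals and Koo-Li interpretation bands), descriptive summaries,
    group comparisons, comparison against dietary reference standards, and
    a seeded synthetic-cohort generator with known ground truth so the
    whole pipeline is testable without licensed nutrient databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
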