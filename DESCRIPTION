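Package: dietprofiler
Title: Rule-Based Diet Quality Profiling, Scoring and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores whole diets on a 1-3 quality scale (green/yellow/orange)
    from five nutrient items (carbohydrate-to-fiber ratio, saturated fat as
    percent of energy, sodium, protein per kg body weight, and total fiber),
    using point cut-offs anchored on EFSA/WHO reference intakes and a
    Nutri-Score-style points aggregation with a protein-exclusion rule for
    high unhealthy-point diets. Adds a fat-to-carbohydrate energy-ratio
    classifier of macronutrient balance, food-group energy profiling against
    a reference pattern, structured dietary-advice codes, a seeded synthetic
    cohort generator (diet, BMI and breast-milk leptin), and a cohort
    statistics harness (ANOVA with LSD letters, stratified Spearman
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
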