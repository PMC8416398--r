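Package: nutriga
Title: Genetic-Algorithm Meal Recommendation and Daily Energy-Balance Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calorie and macronutrient accounting for meals built from a
    food-composition database (Atwater general factors over household serving
    measures), Mifflin-St Jeor basal metabolic rate with physical-activity-level
    multipliers, MET-based exercise energy expenditure, a daily calorie and
    macronutrient deficit ledger with end-of-day reset, and a genetic-algorithm
    meal predictor that searches the food database for meals filling the
    remaining daily deficit subject to macronutrient bounds and optional
    glycemic-index and cholesterol health constraints. Ships a worked-example
    fixture database, a seeded synthetic database generator, and a command-line
    interface for profile setup, diary logging, daily reports and prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
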