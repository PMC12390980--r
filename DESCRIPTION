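Package: nutriplanr
Title: Knowledge-Based Weekly Mediterranean Meal Plan Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A constraint-based recommender for weekly Mediterranean nutrition
    plans. Estimates a user's daily energy requirement from anthropometrics
    (Harris-Benedict basal metabolic rate, physical-activity multiplier, body
    mass index adjustment), filters a dish/meal database by cuisine, season,
    allergies and halal preference, enumerates and scores candidate daily
    plans against caloric and macronutrient targets, and greedily assembles
    seven-day plans under food-group and diversity constraints. Includes a
    synthetic fixture-database and user-cohort generator plus an evaluation
    harness that audits filtering soundness and summarises plan acceptability
    and nutritional accuracy per user stratum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
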