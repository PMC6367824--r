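Package: hrcimpact
Title: Health Impact Assessment of Nutrient-Profile Regulation of
    Health-Related Food Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the population-health consequences of restricting
    health-related claims (HRCs) on pre-packaged food to products that pass
    a nutrient profile model.  Disaggregates per-food-group purchase and
    nutrient-intake data into claim and non-claim streams using claim
    prevalences and purchase odds ratios, constructs counterfactual diets
    under claim-restriction and reformulation scenarios gated by the FSANZ
    Nutrient Profiling Scoring Criterion or a configurable EU-style
    threshold model, and converts diet changes into non-communicable
    disease deaths averted via population impact fractions with direct and
    mediated (body weight, blood pressure, blood cholesterol) pathways.
    Includes a synthetic-data generator emulating the required survey
    inputs, Monte Carlo uncertainty intervals, and tornado-style
    sensitivity decomposition.
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
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
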