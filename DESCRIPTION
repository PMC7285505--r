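Package: dairyheat
Title: Heat-Stress-Aware Modelling of Milk Yield, Quality and Feed Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling daily milk yield, milk composition and
    concentrate feed intake of dairy cows from weather and herd-management
    records. Implements nine temperature-humidity index (THI) variants with
    Magnus dewpoint and bisection wet-bulb derivations, a seeded synthetic
    robotic-dairy-farm generator built on a Wood lactation curve with a
    THI-threshold heat-stress decrement, assembly of a fixed 21-input /
    4-target feature matrix with min-max normalisation and random
    train/test splitting, a two-layer tan-sigmoid feedforward network
    trained by Levenberg-Marquardt under Bayesian regularization (MacKay
    evidence updates), pooled regression diagnostics with
    prediction-interval outlier rates and seasonal summaries, and a
    drafting-gate decision system that routes heat-stressed cows to
    sprinkler cooling with next-day reassessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
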