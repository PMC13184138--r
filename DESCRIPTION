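Package: idiomood
Title: Idiographic Mood Modeling and Personalized Lifestyle Intervention Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses two-phase ecological momentary assessment
    (EMA) plus smartwatch studies of depressed mood. Provides a synthetic
    cohort generator with planted lifestyle-to-mood couplings, feature
    alignment of irregularly sampled streams to the mood sampling grid,
    per-participant (N-of-1) predictive models selected by blocked
    cross-validated MAPE, Shapley-value feature ranking, a structured decision
    algorithm that assigns a personalized lifestyle intervention domain
    (sleep, exercise, diet, social connection), phase-2 slope specificity
    analysis via robust regression, and the repeated-measures, effect-size and
    remission statistics used to evaluate clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nortest,
    zoo,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
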