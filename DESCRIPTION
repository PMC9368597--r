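Package: ohppfwa
Title: Functional Work Ability Scoring and Prognosis from Occupational
    Health Protection Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns free-text occupational health protection profiles (OHPPs)
    into per-body-part functional work ability (FWA) severity scores and uses
    them for prognosis. Provides a rule-based extractor for (body part,
    protection level) pairs with laterality handling and fuzzy keyword
    matching, a work-ability-index style severity scoring allocation, a
    seeded synthetic corpus generator with ground truth for end-to-end
    testing, leakage-safe worker-level splits and folds, a built-in
    least-squares gradient-boosted regression-tree learner with a pluggable
    model registry and RMSLE/R2/MAE evaluation, exact and permutation-sampled
    Shapley attributions satisfying the additive efficiency property, and
    stratified severity-share summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
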