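Package: flightnet
Title: Trajectory-Based Classification of Mosquito Flight Behaviour at Bednets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 2D mosquito flight trajectories recorded around
    insecticide-treated and untreated bednets. Provides a correlated-random-walk
    flight simulator with mortality censoring and tracking gaps, sliding-window
    track segmentation with linear gap interpolation and an information-quality
    filter, kinematic and geometric feature engineering (turn-angle statistics,
    zero-crossing counts, straightness), Mann-Whitney/Bonferroni feature
    screening with Spearman deduplication, imbalance-aware gradient-boosted tree
    classification with Matthews-correlation decision-boundary tuning and
    track-level vote aggregation, trial-level cross-validation with a full
    metric panel and time-resolved accuracy, and Shapley-value feature
    attribution for the fitted ensembles.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
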