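# flightnet

Trajectory-based classification of mosquito flight behaviour at
insecticide-treated and untreated bednets.

Host-seeking mosquitoes tracked around a human-baited bednet produce 2D
flight trajectories (50 frames/s, positions in mm). `flightnet` asks whether
flight behaviour alone can tell an untreated net (UT) from a
permethrin-incorporated Olyset net (OL), and which flight features carry the
signal — evidence for whether the insecticide repels before contact or
irritates after it. The package is aimed at vector-behaviour researchers and
anyone analysing animal-trajectory classification problems with grouped
(trial-level) data.

The pipeline:

* **Segmentation** — tracks shorter than 1 s are dropped, missed detections
  are linearly interpolated, and each track is cut into overlapping
  fixed-duration windows (tuned defaults 7.5 s window, 7 s overlap: a track
  of *n* frames yields ⌊(*n* − 375)/25⌋ + 1 segments at 50 fps). Segments
  with poor information quality (score Σ rᵢ²/L over interpolated runs) are
  removed at a mutual-information-selected threshold.
* **Features** — per segment: velocity components, speed, acceleration,
  absolute wrapped heading change ∈ [0, π], curvature; each summarised by
  mean, SD, min, max and quartiles over *real* positions only, plus
  zero-crossing counts (signed for horizontal/vertical velocity, exact zeros
  for angle change) and path/net-displacement/straightness.
* **Selection** — per-feature two-sided Mann–Whitney U tests, Bonferroni
  family-wise control at α = 0.05, then Spearman deduplication (|ρ| > 0.85
  keeps the member with stronger evidence).
* **Model** — gradient-boosted trees (xgboost) with the UT:OL segment ratio
  as the positive-class weight, Z-score normalisation from training
  statistics, a decision boundary tuned over {0.01, …, 0.99} by Matthews
  correlation, and track calls by majority vote over segment calls.
* **Evaluation** — trial-level cross-validation (whole trials held out;
  tuning and modelling trials disjoint), a 13-metric panel reported with
  both classes as positive, true-class-normalised confusion matrices, and
  time-resolved accuracy in 5-min bins.
* **Explanation** — exact tree-path Shapley values per segment in log-odds
  space, ranked by mean |SHAP|.

Because the original tracking data are not redistributable, the package
includes a correlated-random-walk flight simulator
(`simulate_track/trial/study`) with behavioural presets for the two regimes,
mortality censoring (susceptible mosquitoes at OL produce no tracks after
30 min) and tracking gaps, so the whole pipeline is testable end-to-end.

## Worked example

```r
library(flightnet)

# a small two-regime study: 4 UT and 4 OL trials, 15 mosquitoes each, 30 min
study <- simulate_study(4, 4, n_mosquitoes = 15, duration_s = 1800,
                        seed = 424)
study
#> <flight_study>
#>   trials: 8 (4 UT, 4 OL)
#>   tracks: 120, positions: 106378

cfg <- study_config(n_folds = 4, n_train = 4, n_test = 2,
                    test_ut_per_strain = NULL, test_ol_per_strain = NULL,
                    tuning_fraction = 0.25, nrounds = 60, seed = 3)
report <- run_pipeline(study, cfg)   # ~12 s
report
#> <study_report>
#>   trials: 8 (2 tuning / 6 modelling), folds: 4
#>   balanced accuracy: 0.972 (0.938-1.000)
#>   ROC AUC: 1.000 (1.000-1.000)
#>   selected features: 12; decision boundaries tuned per fold

head(report$importance, 3)
#> # A tibble: 3 x 4
#>   feature                     mean_abs_shap direction  rank
#>   <chr>                               <dbl>     <dbl> <int>
#> 1 accel_q1                             1.96          1     1
#> 2 angle_change_median                  1.75          1     2
#> 3 angle_change_zero_crossings          1.32         -1     3
```

The balanced accuracy of 0.972 (mean of per-class recalls over held-out
trials) says tracks from the two simulated regimes are almost perfectly
separable at track level even in this small study. The importance table
reads: high lower-quartile acceleration and large typical angle changes push
segments toward the OL class (direction +1) — even the calmest stretches of
an OL segment turn hard and fast; many exact-zero angle changes (straight or
resting stretches) push toward UT (direction −1). At the full study scale
used by `scripts/acceptance.R` the three headline discriminators are the
zero-count and lower quartile of angle change and the horizontal-velocity
zero-crossing count. `tidy(report)` returns the full metric panel;
`autoplot(report, "confusion")`, `autoplot(report, "time")` and
`autoplot(report, "importance")` draw the standard figures.

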