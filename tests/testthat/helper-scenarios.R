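# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small two-regime study: 4 + 4 trials, a few short-lived mosquitoes each.
small_contrast_study <- function() {
  cached("small_study", function() {
    simulate_study(4, 4, n_mosquitoes = 6, duration_s = 900,
                   track_meanlog = log(15), track_sdlog = 0.5, seed = 424)
  })
}

# Its feature table (segments labelled by trial metadata).
small_feature_table <- function() {
  cached("small_ft", function() {
    study <- small_contrast_study()
    tracks <- interpolate_gaps(filter_min_duration(study$tracks, 1))
    segs <- window_tracks(tracks, study$trials)
    build_feature_table(tracks, segs)
  })
}

# A fitted bundle on the small study, for prediction/explanation tests.
small_bundle <- function() {
  cached("small_bundle", function() {
    ft <- small_feature_table()
    feats <- c("angle_change_q1", "vx_zero_crossings", "speed_mean",
               "angle_change_zero_crossings", "straightness")
    cfg <- study_config(nrounds = 40, seed = 7)
    fit_model_bundle(ft, feats, cfg, seed = 7)
  })
}

# Pipeline configuration scaled for the small study.
small_config <- function(seed = 3) {
  study_config(n_folds = 2, n_train = 4, n_test = 2,
               test_ut_per_strain = NULL, test_ol_per_strain = NULL,
               tuning_fraction = 0.25, nrounds = 30, seed = seed)
}

# A random-walk segment with optional interpolated stretches.
random_segment <- function(n = 40, gap = TRUE) {
  x <- cumsum(stats::rnorm(n, sd = 4))
  y <- cumsum(stats::rnorm(n, sd = 4))
  real <- rep(TRUE, n)
  if (gap && n > 10) {
    k <- sample(3:6, 1)
    s <- sample(2:(n - k - 1), 1)
    real[s:(s + k - 1)] <- FALSE
  }
  tibble::tibble(trial_id = "T", track_id = "t", frame = seq_len(n) - 1L,
                 t_s = (seq_len(n) - 1L) / 50, x_mm = x, y_mm = y,
                 real_flag = real)
}

# A straight-line track table with the canonical columns.
toy_track <- function(frames, x, y, trial = "T1", track = "a", fps = 50,
                      real = TRUE) {
  tibble::tibble(trial_id = trial, track_id = track,
                 frame = as.integer(frames), t_s = frames / fps,
                 x_mm = x, y_mm = y,
                 real_flag = rep_len(real, length(frames)))
}

# A tiny xgboost model over d features for Shapley tests.
toy_booster <- function(n = 60, d = 4, nrounds = 12, depth = 3, seed = 3) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + stats::rnorm(n, sd = 0.3) > 0)
  booster <- train_classifier(X, ifelse(y == 1, "OL", "UT"),
                              max_depth = depth, nrounds = nrounds,
                              eta = 0.3, subsample = 1, seed = seed)
  list(booster = booster, X = X)
}
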