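# End-to-end orchestration: simulate/load -> segment -> quality filter ->
# features -> tuning/modelling split -> folds -> per-fold train/tune/predict
# -> metrics, time-resolved accuracy and Shapley attributions.

#' Assert that two trial sets are disjoint
#'
#' Leakage guard used by the pipeline between the tuning and modelling splits
#' and between the train and test sides of every fold.
#'
#' @param a,b Character vectors of trial ids.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors on overlap.
#' @export
assert_disjoint_trials <- function(a, b, what = "trial sets") {
  overlap <- intersect(a, b)
  if (length(overlap) > 0) {
    stop(sprintf("leakage: %s share trial(s): %s", what,
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Segment + featurise a track table. Returns the feature table and a stage log.
prepare_features <- function(tracks, trials, config) {
  log <- list()
  n0 <- nrow(dplyr::distinct(tracks, .data$trial_id, .data$track_id))
  kept <- filter_min_duration(tracks, config$min_track_duration_s)
  n1 <- nrow(dplyr::distinct(kept, .data$trial_id, .data$track_id))
  log$min_duration <- c(n_in = n0, n_out = n1)
  if (nrow(kept) == 0) stop("no tracks remain after the duration filter", call. = FALSE)

  interp <- interpolate_gaps(kept)
  segs <- window_tracks(interp, trials, window_s = config$window_s,
                        overlap_s = config$overlap_s, fps = config$fps)
  log$windowing <- c(n_in = n1, n_out = nrow(segs))
  if (nrow(segs) == 0) stop("windowing produced no segments", call. = FALSE)

  ft <- build_feature_table(interp, segs, fps = config$fps,
                            magnitude_zero_crossings = config$magnitude_zero_crossings,
                            zero_tol = config$zero_tol)
  log$features <- c(n_in = nrow(segs), n_out = nrow(ft))
  list(features = ft, log = log)
}

# Split trials into tuning and modelling sets, stratified by net type and
# strain, seeded.
split_tuning_modelling <- function(trials, tuning_fraction, seed) {
  local_seed(seed, {
    tuning <- character()
    for (net in unique(trials$net_type)) {
      sub <- trials[trials$net_type == net, , drop = FALSE]
      pools <- split(sub$trial_id, sub$strain)
      sizes <- lengths(pools)
      target <- round(nrow(sub) * tuning_fraction)
      # largest-remainder allocation of this net's budget over strains
      raw <- target * sizes / sum(sizes)
      alloc <- floor(raw)
      rem_order <- order(raw - alloc, stats::runif(length(pools)),
                         decreasing = TRUE)
      short <- target - sum(alloc)
      k <- 0L
      while (short > 0L && k < length(pools)) {
        k <- k + 1L
        i <- rem_order[k]
        if (alloc[i] < sizes[i]) {
          alloc[i] <- alloc[i] + 1L
          short <- short - 1L
        }
      }
      tuning <- c(tuning, unlist(purrr::map2(pools, alloc, function(pool, n_t) {
        if (n_t > 0) pool[sample.int(length(pool), n_t)] else character()
      }), use.names = FALSE))
    }
    modelling <- setdiff(trials$trial_id, tuning)
    list(tuning = sort(tuning), modelling = sort(modelling))
  })
}

#' Evaluate folds of a feature table
#'
#' For each fold: assembles the training set under the configured strategy,
#' fits the normaliser + boosted-tree bundle, tunes the decision boundary on
#' training probabilities, predicts the test-trial tracks and computes the
#' metric panel. Train/test disjointness is asserted for every fold.
#'
#' @param feature_table Feature tibble (quality-filtered).
#' @param folds Fold tibble from [generate_folds()].
#' @param features Selected feature names.
#' @param config A [study_config()].
#' @return A list with `fold_metrics` (tibble), `predictions` (tibble with a
#'   `fold` column) and `bundles` (list of fitted `model_bundle`s).
#' @export
evaluate_folds <- function(feature_table, folds, features, config = study_config()) {
  results <- purrr::map(seq_len(nrow(folds)), function(i) {
    train_ids <- folds$train_trials[[i]]
    test_ids <- folds$test_trials[[i]]
    assert_disjoint_trials(train_ids, test_ids,
                           sprintf("fold %d train/test", folds$fold[i]))
    train_ft <- feature_table[feature_table$trial_id %in% train_ids, , drop = FALSE]
    test_ft <- feature_table[feature_table$trial_id %in% test_ids, , drop = FALSE]
    if (length(unique(train_ft$net_type)) < 2) {
      stop(sprintf("fold %d: training trials contain a single class",
                   folds$fold[i]), call. = FALSE)
    }
    train_set <- build_training_set(train_ft, strategy = config$strategy,
                                    seed = derive_seed(config$seed, 1000L + i),
                                    early_cutoff_s = config$early_cutoff_s)
    bundle <- fit_model_bundle(train_set, features, config,
                               seed = derive_seed(config$seed, 2000L + i))
    preds <- predict_tracks(bundle, test_ft)
    preds$fold <- folds$fold[i]
    metrics <- compute_metrics(preds$track_call, preds$track_score,
                               preds$net_type)
    metrics$fold <- folds$fold[i]
    list(metrics = metrics, predictions = preds, bundle = bundle)
  })
  list(
    fold_metrics = dplyr::bind_rows(purrr::map(results, "metrics")) |>
      dplyr::relocate("fold"),
    predictions = dplyr::bind_rows(purrr::map(results, "predictions")),
    bundles = purrr::map(results, "bundle")
  )
}

#' Run the full study pipeline
#'
#' Executes the end-to-end analysis on a simulated or loaded study:
#' duration filter, gap interpolation, sliding-window segmentation,
#' feature extraction, tuning/modelling trial split, mutual-information
#' quality threshold and Mann-Whitney/Bonferroni/Spearman feature selection
#' (both frozen on the tuning split), trial-level cross-validation with the
#' configured training strategy and decision-boundary tuning, the metric
#' panel, the true-class-normalised confusion matrix, time-resolved accuracy
#' and Shapley attributions for the best fold. Fully reproducible under
#' `config$seed`.
#'
#' @param study A `flight_study` (from [simulate_study()]) or a list with
#'   elements `tracks` and `trials`.
#' @param config A [study_config()].
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(study, config = study_config()) {
  if (!all(c("tracks", "trials") %in% names(study))) {
    stop("`study` must have `tracks` and `trials` elements", call. = FALSE)
  }
  tracks <- study$tracks
  trials <- tibble::as_tibble(study$trials)
  if (length(unique(trials$net_type)) < 2) {
    stop("fold construction requires both net-type labels in the study", call. = FALSE)
  }

  prep <- prepare_features(tracks, trials, config)
  ft <- prep$features
  log <- prep$log

  splits <- split_tuning_modelling(trials, config$tuning_fraction,
                                   derive_seed(config$seed, 11L))
  assert_disjoint_trials(splits$tuning, splits$modelling, "tuning/modelling sets")
  tune_ft <- ft[ft$trial_id %in% splits$tuning, , drop = FALSE]
  model_ft <- ft[ft$trial_id %in% splits$modelling, , drop = FALSE]
  if (length(unique(model_ft$net_type)) < 2) {
    stop("modelling split contains a single class; cannot build folds", call. = FALSE)
  }

  quality_threshold <- Inf
  if (isTRUE(config$select_quality) && nrow(tune_ft) > 0 &&
      length(unique(tune_ft$net_type)) >= 2) {
    qt <- select_quality_threshold(
      tune_ft[, feature_columns(tune_ft), drop = FALSE],
      quality = tune_ft$quality, labels = tune_ft$net_type,
      grid = config$quality_grid, bins = config$mi_bins)
    quality_threshold <- qt$threshold
    n_in <- nrow(ft)
    ft <- apply_quality_filter(ft, quality_threshold)
    tune_ft <- apply_quality_filter(tune_ft, quality_threshold)
    model_ft <- apply_quality_filter(model_ft, quality_threshold)
    log$quality_filter <- c(n_in = n_in, n_out = nrow(ft))
  }

  selection <- select_features(
    if (nrow(tune_ft) > 0 && length(unique(tune_ft$net_type)) >= 2) tune_ft else model_ft,
    labels = if (nrow(tune_ft) > 0 && length(unique(tune_ft$net_type)) >= 2)
      tune_ft$net_type else model_ft$net_type,
    alpha = config$alpha, rho_threshold = config$rho)
  features <- selection$features
  if (length(features) == 0) {
    stop("no features survive selection; cannot fit the classifier", call. = FALSE)
  }

  model_trials <- trials[trials$trial_id %in% splits$modelling, , drop = FALSE]
  folds <- generate_folds(
    model_trials, n_folds = config$n_folds, n_train = config$n_train,
    n_test = config$n_test, ut_per_strain = config$test_ut_per_strain,
    ol_per_strain = config$test_ol_per_strain,
    seed = derive_seed(config$seed, 12L))

  ev <- evaluate_folds(model_ft, folds, features, config)
  preds <- ev$predictions

  confusion <- confusion_normalized(preds$track_call, preds$net_type,
                                    fold = preds$fold)
  time_acc <- time_resolved_accuracy(preds, bin_s = 300,
                                     duration_s = max(7200, preds$start_s),
                                     cutoff_s = config$early_cutoff_s)

  best_fold <- ev$fold_metrics$fold[which.max(ev$fold_metrics$balanced_accuracy)]
  best_idx <- which(folds$fold == best_fold)
  best_test <- model_ft[model_ft$trial_id %in% folds$test_trials[[best_idx]], ,
                        drop = FALSE]
  attributions <- attribute_segments(ev$bundles[[best_idx]], best_test)
  importance <- rank_features(attributions)

  agg <- ev$fold_metrics |>
    dplyr::select(-"fold") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     min = min(.data$value, na.rm = TRUE),
                     max = max(.data$value, na.rm = TRUE), .groups = "drop")

  structure(
    list(
      config = config, trials = trials, splits = splits,
      quality_threshold = quality_threshold, selection = selection,
      folds = folds, fold_metrics = ev$fold_metrics, metrics = agg,
      predictions = preds, confusion = confusion, time_accuracy = time_acc,
      best_fold = best_fold, attributions = attributions,
      importance = importance, log = log
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  trials: %d (%d tuning / %d modelling), folds: %d\n",
              nrow(x$trials), length(x$splits$tuning),
              length(x$splits$modelling), nrow(x$folds)))
  ba <- x$metrics[x$metrics$metric == "balanced_accuracy", ]
  cat(sprintf("  balanced accuracy: %.3f (%.3f-%.3f)\n",
              ba$mean, ba$min, ba$max))
  auc <- x$metrics[x$metrics$metric == "roc_auc", ]
  cat(sprintf("  ROC AUC: %.3f (%.3f-%.3f)\n", auc$mean, auc$min, auc$max))
  cat(sprintf("  selected features: %d; decision boundaries tuned per fold\n",
              length(x$selection$features)))
  invisible(x)
}

#' Grid search over windowing and model hyperparameters
#'
#' Runs the segmentation-to-evaluation pipeline on the tuning trials for
#' every combination of window length, overlap and model hyperparameters,
#' and returns the configuration with the highest mean track-level balanced
#' accuracy. Ties resolve to the smaller window, then the larger overlap
#' (more data). Grid points producing no segments are skipped with a
#' warning.
#'
#' @param tracks Track tibble restricted to the tuning trials.
#' @param trials Metadata of the tuning trials (both classes present).
#' @param window_grid,overlap_grid Numeric grids in seconds.
#' @param model_grid Data frame of hyperparameter combinations with columns
#'   among `max_depth`, `nrounds`, `eta`, `subsample`; default: the values in
#'   `config`.
#' @param config Base [study_config()]; `n_folds`/`n_train`/`n_test` control
#'   the inner cross-validation on the tuning trials.
#' @return A list with `best_config` (a `study_config`) and `results` (tibble
#'   of grid points and their mean balanced accuracy).
#' @export
grid_search <- function(tracks, trials, window_grid, overlap_grid,
                        model_grid = NULL, config = study_config()) {
  if (is.null(model_grid)) {
    model_grid <- data.frame(max_depth = config$max_depth,
                             nrounds = config$nrounds,
                             eta = config$eta, subsample = config$subsample)
  }
  grid <- expand.grid(window_s = window_grid, overlap_s = overlap_grid,
                      model = seq_len(nrow(model_grid)))
  grid <- grid[grid$overlap_s < grid$window_s, , drop = FALSE]
  if (nrow(grid) == 0) stop("empty grid after removing invalid overlaps", call. = FALSE)

  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$window_s <- grid$window_s[g]
    cfg$overlap_s <- grid$overlap_s[g]
    for (h in names(model_grid)) cfg[[h]] <- model_grid[[h]][grid$model[g]]
    res <- tryCatch({
      prep <- prepare_features(tracks, trials, cfg)
      ft <- prep$features
      sel <- select_features(ft, ft$net_type, alpha = cfg$alpha,
                             rho_threshold = cfg$rho)
      if (length(sel$features) == 0) stop("no features selected")
      folds <- generate_folds(trials, n_folds = cfg$n_folds,
                              n_train = cfg$n_train, n_test = cfg$n_test,
                              ut_per_strain = cfg$test_ut_per_strain,
                              ol_per_strain = cfg$test_ol_per_strain,
                              seed = derive_seed(cfg$seed, 13L))
      ev <- evaluate_folds(ft, folds, sel$features, cfg)
      mean(ev$fold_metrics$balanced_accuracy)
    }, error = function(e) {
      warning(sprintf("grid point (window %.3g s, overlap %.3g s) skipped: %s",
                      cfg$window_s, cfg$overlap_s, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
    tibble::tibble(window_s = grid$window_s[g], overlap_s = grid$overlap_s[g],
                   model = grid$model[g], balanced_accuracy = res)
  }) |> dplyr::bind_rows()

  ok <- rows[!is.na(rows$balanced_accuracy), , drop = FALSE]
  if (nrow(ok) == 0) stop("every grid point failed", call. = FALSE)
  ok <- ok[order(-ok$balanced_accuracy, ok$window_s, -ok$overlap_s), ,
           drop = FALSE]
  best <- config
  best$window_s <- ok$window_s[1]
  best$overlap_s <- ok$overlap_s[1]
  for (h in names(model_grid)) best[[h]] <- model_grid[[h]][ok$model[1]]
  list(best_config = best, results = rows)
}
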