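# Training-set assembly, normalisation, boosted-tree classification,
# decision-boundary tuning and track-level aggregation. The positive class is
# OL (Olyset) throughout.

track_start_times <- function(feature_table) {
  feature_table |>
    dplyr::group_by(.data$trial_id, .data$track_id) |>
    dplyr::summarise(track_start_s = min(.data$start_s), .groups = "drop")
}

#' Assemble the training rows under a training strategy
#'
#' Strategies (sampling is at track level; segments follow their track):
#' * `balanced`: all OL/IS tracks starting within `early_cutoff_s`; the
#'   OL/IR, UT/IS and UT/IR track sets are each subsampled without
#'   replacement (seeded) down to that OL/IS track count (kept whole if
#'   already smaller).
#' * `early`: all tracks starting within `early_cutoff_s` (inclusive).
#' * `comprehensive`: every track.
#'
#' @param feature_table Feature tibble with `net_type`, `resistance` and
#'   `start_s` columns.
#' @param strategy `"balanced"`, `"early"` or `"comprehensive"`.
#' @param seed Integer seed for the subsampling.
#' @param early_cutoff_s Start-time cutoff in seconds (default 1800).
#' @return The subset of `feature_table` rows forming the training set.
#' @export
build_training_set <- function(feature_table,
                               strategy = c("balanced", "early", "comprehensive"),
                               seed = 1L, early_cutoff_s = 1800) {
  strategy <- match.arg(strategy)
  if (strategy == "comprehensive") return(feature_table)
  starts <- track_start_times(feature_table)
  ft <- dplyr::left_join(feature_table, starts, by = c("trial_id", "track_id"))
  if (strategy == "early") {
    out <- ft[ft$track_start_s <= early_cutoff_s, , drop = FALSE]
    out$track_start_s <- NULL
    return(out)
  }
  # balanced
  tracks <- dplyr::distinct(ft, .data$trial_id, .data$track_id,
                            .data$net_type, .data$resistance,
                            .data$track_start_s)
  ref <- tracks[tracks$net_type == "OL" & tracks$resistance == "IS" &
                  tracks$track_start_s <= early_cutoff_s, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("balanced strategy: no OL/IS tracks start within the cutoff", call. = FALSE)
  }
  n_ref <- nrow(ref)
  keep <- ref[, c("trial_id", "track_id")]
  local_seed(seed, {
    for (grp in list(c("OL", "IR"), c("UT", "IS"), c("UT", "IR"))) {
      g <- tracks[tracks$net_type == grp[1] & tracks$resistance == grp[2], ,
                  drop = FALSE]
      if (nrow(g) > n_ref) {
        g <- g[sample.int(nrow(g), n_ref), , drop = FALSE]
      }
      keep <- dplyr::bind_rows(keep, g[, c("trial_id", "track_id")])
    }
  })
  out <- dplyr::semi_join(ft, keep, by = c("trial_id", "track_id"))
  out$track_start_s <- NULL
  out
}

#' Fit a Z-score normaliser on training rows
#'
#' @param train Data frame or matrix of training feature values.
#' @param features Feature names to normalise (default: all columns).
#' @return A list with per-feature `center` and `scale`; features with zero
#'   training standard deviation get scale 1 (their normalised values are all
#'   zero) with a warning.
#' @export
fit_zscore <- function(train, features = colnames(train)) {
  X <- as.matrix(as.data.frame(train)[, features, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  degenerate <- scale == 0 | !is.finite(scale)
  if (any(degenerate)) {
    warning(sprintf("constant training feature(s): %s (emitted as all-zero)",
                    paste(features[degenerate], collapse = ", ")), call. = FALSE)
    scale[degenerate] <- 1
  }
  list(center = center, scale = scale, features = features)
}

#' Apply a fitted Z-score normaliser
#'
#' @param norm A normaliser from [fit_zscore()].
#' @param rows Data frame or matrix with the feature columns.
#' @return A numeric matrix of normalised values.
#' @export
apply_zscore <- function(norm, rows) {
  X <- as.matrix(as.data.frame(rows)[, norm$features, drop = FALSE])
  scale(X, center = norm$center, scale = norm$scale)[, , drop = FALSE]
}

#' Train the gradient-boosted tree classifier
#'
#' Binary gradient-boosted decision trees (xgboost) with the OL class
#' positive and the positive class re-weighted by `class_weight` (the
#' UT-to-OL segment ratio of the training set). Deterministic under the seed.
#'
#' @param X Numeric training matrix (rows = segments).
#' @param labels Vector of `"UT"`/`"OL"` labels.
#' @param class_weight Positive-class weight; `NULL` computes the UT/OL
#'   training ratio.
#' @param max_depth,nrounds,eta,subsample Hyperparameters (defaults 4, 200,
#'   0.1, 0.8).
#' @param seed Integer seed.
#' @return An `xgb.Booster` with the class weight stored as an attribute.
#' @export
train_classifier <- function(X, labels, class_weight = NULL,
                             max_depth = 4, nrounds = 200, eta = 0.1,
                             subsample = 0.8, seed = 1L) {
  y <- as.integer(labels == "OL")
  if (length(unique(y)) < 2) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  if (is.null(class_weight)) class_weight <- sum(y == 0) / sum(y == 1)
  if (!is.finite(class_weight) || class_weight <= 0) {
    stop("`class_weight` must be a positive finite number", call. = FALSE)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      max_depth = max_depth, eta = eta, subsample = subsample,
      scale_pos_weight = class_weight,
      nthread = 1, seed = as.integer(seed)
    ),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  attr(booster, "class_weight") <- class_weight
  booster
}

# Matthews correlation coefficient of binary calls vs truth (OL positive);
# any zero denominator factor gives 0.
mcc_binary <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Tune the decision boundary by Matthews correlation
#'
#' Sweeps the decision boundary over the grid `{0.01, 0.02, ..., 0.99}` on
#' training probabilities and returns the boundary with the largest Matthews
#' correlation coefficient (probability `>= tau` predicts OL). Ties resolve
#' to the smallest boundary; an MCC with a zero denominator is defined as 0.
#'
#' @param probs Training-set OL probabilities.
#' @param labels Training labels (`"UT"`/`"OL"`).
#' @return The tuned boundary `tau`.
#' @export
tune_decision_boundary <- function(probs, labels) {
  truth <- labels == "OL"
  if (length(unique(truth)) < 2) {
    stop("boundary tuning requires both classes", call. = FALSE)
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  mcc <- vapply(grid, function(tau) mcc_binary(probs >= tau, truth), numeric(1))
  grid[which.max(mcc)]  # which.max takes the first (smallest tau) on ties
}

#' Fit the full model bundle on a training table
#'
#' Convenience wrapper chaining [fit_zscore()], [train_classifier()] (with
#' the UT:OL segment-count weight) and [tune_decision_boundary()] on the
#' training rows.
#'
#' @param train_table Feature tibble of training segments with `net_type`.
#' @param features Selected feature names.
#' @param config A [study_config()] for hyperparameters.
#' @param seed Integer seed.
#' @return An object of class `model_bundle`: normaliser, booster, tuned
#'   boundary `tau`, class weight, feature names and strategy tag.
#' @export
fit_model_bundle <- function(train_table, features, config = study_config(),
                             seed = 1L) {
  labels <- train_table$net_type
  norm <- fit_zscore(train_table, features)
  X <- apply_zscore(norm, train_table)
  weight <- sum(labels == "UT") / sum(labels == "OL")
  booster <- train_classifier(
    X, labels, class_weight = weight,
    max_depth = config$max_depth, nrounds = config$nrounds,
    eta = config$eta, subsample = config$subsample, seed = seed
  )
  probs <- stats::predict(booster, xgboost::xgb.DMatrix(X))
  tau <- tune_decision_boundary(probs, labels)
  structure(
    list(normaliser = norm, booster = booster, tau = tau,
         class_weight = weight, features = features,
         strategy = config$strategy),
    class = "model_bundle"
  )
}

#' Per-segment OL probabilities from a fitted bundle
#'
#' @param bundle A `model_bundle`.
#' @param feature_table Feature tibble whose columns include the bundle's
#'   feature list.
#' @return Numeric vector of OL probabilities, one per row.
#' @export
predict_segments <- function(bundle, feature_table) {
  missing <- setdiff(bundle$features, names(feature_table))
  if (length(missing) > 0) {
    stop(sprintf("feature table lacks model feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- apply_zscore(bundle$normaliser, feature_table)
  stats::predict(bundle$booster, xgboost::xgb.DMatrix(X))
}

#' Aggregate segment predictions to track predictions
#'
#' Each segment is called OL when its probability is `>= tau`; the track call
#' is the mode (majority) of its segment calls, with exact ties resolved by
#' comparing the mean segment probability against `tau`. The track score is
#' the mean segment probability.
#'
#' @param bundle A `model_bundle`.
#' @param feature_table Feature tibble of the segments to score (grouped by
#'   track via `trial_id`/`track_id`).
#' @return A tibble with one row per track: provenance, `n_segments`,
#'   `track_score`, `track_call` and (when present) the true `net_type`.
#' @export
predict_tracks <- function(bundle, feature_table) {
  probs <- predict_segments(bundle, feature_table)
  aggregate_track_predictions(feature_table, probs, bundle$tau)
}

#' Aggregate per-segment probabilities to track calls
#'
#' Implements the vote aggregation used by [predict_tracks()]: segment call =
#' probability `>= tau`; track call = majority of segment calls; an exact tie
#' goes to OL iff the mean segment probability is `>= tau`.
#'
#' @param feature_table Tibble with `trial_id`, `track_id`, `start_s` and
#'   optional label columns, one row per segment.
#' @param probs OL probability per segment row.
#' @param tau Decision boundary.
#' @return One row per track with `n_segments`, `track_score`, `track_call`.
#' @export
aggregate_track_predictions <- function(feature_table, probs, tau) {
  df <- feature_table[, intersect(c("trial_id", "track_id", "start_s",
                                    "net_type", "strain", "resistance"),
                                  names(feature_table))]
  df$.prob <- probs
  df$.call <- probs >= tau
  out <- df |>
    dplyr::group_by(.data$trial_id, .data$track_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      track_score = mean(.data$.prob),
      n_ol_calls = sum(.data$.call),
      start_s = min(.data$start_s),
      dplyr::across(dplyr::any_of(c("net_type", "strain", "resistance")),
                    dplyr::first),
      .groups = "drop"
    )
  out$track_call <- ifelse(
    out$n_ol_calls * 2L == out$n_segments,
    ifelse(out$track_score >= tau, "OL", "UT"),
    ifelse(out$n_ol_calls * 2L > out$n_segments, "OL", "UT")
  )
  out$n_ol_calls <- NULL
  out
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>\n")
  cat(sprintf("  features: %d; decision boundary: %.2f; UT:OL weight: %.3f; strategy: %s\n",
              length(x$features), x$tau, x$class_weight, x$strategy))
  invisible(x)
}
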