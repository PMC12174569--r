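#' Read a track table from delimited text
#'
#' The on-disk format is plain CSV with columns `trial_id`, `track_id`,
#' `frame`, `t_s`, `x_mm`, `y_mm` and optionally `real_flag` (defaulting to
#' `TRUE` on input). Rows are sorted by (trial, track, frame); duplicated
#' frame indices within a track are rejected.
#'
#' @param path Path to a CSV file with a header row.
#' @return A track tibble.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "track_id", "frame", "t_s", "x_mm", "y_mm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("frame", "t_s", "x_mm", "y_mm")) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1]
      stop(sprintf("non-numeric value in column `%s` at data row %d", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  if (is.null(raw$real_flag)) raw$real_flag <- TRUE
  raw$real_flag <- as.logical(raw$real_flag)
  raw$trial_id <- as.character(raw$trial_id)
  raw$track_id <- as.character(raw$track_id)
  raw$frame <- as.integer(raw$frame)

  out <- dplyr::arrange(tibble::as_tibble(raw[, track_columns()]),
                        .data$trial_id, .data$track_id, .data$frame)
  dup <- duplicated(out[, c("trial_id", "track_id", "frame")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicated frame index: trial %s, track %s, frame %d (row %d)",
                 out$trial_id[i], out$track_id[i], out$frame[i], i), call. = FALSE)
  }
  out
}

#' Write a track table to delimited text
#'
#' Deterministic row order (trial, track, frame) and canonical column order, so
#' write--read--write round-trips are byte-identical.
#'
#' @param tracks A track tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  assert_track_table(tracks)
  out <- dplyr::arrange(tracks[, track_columns()],
                        .data$trial_id, .data$track_id, .data$frame)
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trial metadata from CSV
#'
#' @param path CSV with columns `trial_id`, `net_type`, `strain`, `resistance`.
#' @return A tibble of trial metadata.
#' @export
read_trial_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "net_type", "strain", "resistance")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  raw$trial_id <- as.character(raw$trial_id)
  tibble::as_tibble(raw)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the tuned defaults:
#' a 7.5 s window with 7 s overlap at 50 frames/s, a 1 s minimum track
#' duration, Bonferroni FWER 0.05 feature screening with Spearman 0.85
#' deduplication, and the balanced training strategy.
#'
#' @param window_s Segment window length, seconds (default 7.5).
#' @param overlap_s Overlap between consecutive windows, seconds (default 7).
#' @param fps Frames per second (default 50).
#' @param min_track_duration_s Minimum observed track duration kept, seconds.
#' @param quality_grid Candidate quality thresholds; `NULL` (default) uses the
#'   deciles of the observed nonzero qualities plus 0.
#' @param mi_bins Equal-frequency bins for the mutual-information estimator.
#' @param select_quality If `TRUE` (default), select and apply the
#'   mutual-information quality threshold; otherwise keep all segments.
#' @param alpha Family-wise error rate for Bonferroni selection (default 0.05).
#' @param rho Spearman correlation threshold for deduplication (default 0.85).
#' @param magnitude_zero_crossings Emit zero-crossing counts also for the
#'   non-negative magnitude series (speed, acceleration, curvature). Default
#'   `FALSE`: only `vx`, `vy` and `angle_change` carry them.
#' @param zero_tol Tolerance for the exact-zero test in zero-crossing counts
#'   (default 0: exact).
#' @param max_depth,nrounds,eta,subsample Gradient-boosted tree
#'   hyperparameters (defaults 4, 200, 0.1, 0.8).
#' @param strategy Training strategy: `"balanced"` (default), `"early"` or
#'   `"comprehensive"`.
#' @param early_cutoff_s Start-time cutoff used by the balanced and early
#'   strategies, seconds (default 1800).
#' @param n_folds,n_train,n_test Cross-validation shape (defaults 30, 12, 9).
#' @param test_ut_per_strain,test_ol_per_strain Per-strain test composition
#'   (defaults 1 and 2); set both to `NULL` for class-stratified test sets
#'   without strain composition.
#' @param tuning_fraction Fraction of trials held out as the tuning split used
#'   for feature selection and threshold choice (default 0.45).
#' @param seed Master seed for every stochastic stage.
#'
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(window_s = 7.5, overlap_s = 7, fps = 50,
                         min_track_duration_s = 1,
                         quality_grid = NULL, mi_bins = 10,
                         select_quality = TRUE,
                         alpha = 0.05, rho = 0.85,
                         magnitude_zero_crossings = FALSE, zero_tol = 0,
                         max_depth = 4, nrounds = 200, eta = 0.1,
                         subsample = 0.8,
                         strategy = c("balanced", "early", "comprehensive"),
                         early_cutoff_s = 1800,
                         n_folds = 30, n_train = 12, n_test = 9,
                         test_ut_per_strain = 1, test_ol_per_strain = 2,
                         tuning_fraction = 0.45, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot_scalar(window_s, "window_s", lower = 1e-9)
  stopifnot_scalar(overlap_s, "overlap_s", lower = 0)
  if (overlap_s >= window_s) stop("`overlap_s` must be < `window_s`", call. = FALSE)
  stopifnot_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  stopifnot_scalar(rho, "rho", lower = 1e-12, upper = 1)
  structure(
    list(
      window_s = window_s, overlap_s = overlap_s, fps = fps,
      min_track_duration_s = min_track_duration_s,
      quality_grid = quality_grid, mi_bins = mi_bins,
      select_quality = select_quality,
      alpha = alpha, rho = rho,
      magnitude_zero_crossings = magnitude_zero_crossings, zero_tol = zero_tol,
      max_depth = max_depth, nrounds = nrounds, eta = eta, subsample = subsample,
      strategy = strategy, early_cutoff_s = early_cutoff_s,
      n_folds = n_folds, n_train = n_train, n_test = n_test,
      test_ut_per_strain = test_ut_per_strain,
      test_ol_per_strain = test_ol_per_strain,
      tuning_fraction = tuning_fraction, seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [study_config()]; missing keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(study_config, vals)
}
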