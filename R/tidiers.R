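# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return The per-feature test table: `feature`, `U`, `p_value`,
#'   `selected_fwer`, `kept`.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  out <- x$table
  if (is.null(out$kept)) out$kept <- out$feature %in% x$features
  out
}

#' @rdname tidy.selection_report
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$table),
    n_fwer_selected = sum(x$table$selected_fwer),
    n_kept = length(x$features),
    alpha = x$alpha,
    rho_threshold = x$rho_threshold
  )
}

#' Tidy a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return The aggregated metric panel: `metric`, `mean`, `min`, `max`
#'   across folds.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.study_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  pick <- function(m) x$metrics$mean[x$metrics$metric == m]
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_tuning = length(x$splits$tuning),
    n_modelling = length(x$splits$modelling),
    n_folds = nrow(x$folds),
    n_features = length(x$selection$features),
    balanced_accuracy = pick("balanced_accuracy"),
    roc_auc = pick("roc_auc"),
    mcc = pick("mcc")
  )
}

#' Tidy a model bundle
#'
#' @param x A `model_bundle`.
#' @param ... Unused.
#' @return Gain-based importance of the boosted-tree ensemble per feature.
#' @method tidy model_bundle
#' @export
tidy.model_bundle <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain,
                 cover = imp$Cover, frequency = imp$Frequency)
}

#' Tidy an attribution table
#'
#' @param x An `attribution_table`.
#' @param ... Unused.
#' @return A long tibble: one row per segment and feature with the Shapley
#'   `value` and the (normalised) feature value.
#' @method tidy attribution_table
#' @export
tidy.attribution_table <- function(x, ...) {
  shap <- x$shap
  shap$.row <- seq_len(nrow(shap))
  long <- tidyr::pivot_longer(shap, -".row", names_to = "feature",
                              values_to = "value")
  feats <- x$features
  feats$.row <- seq_len(nrow(feats))
  fl <- tidyr::pivot_longer(feats, -".row", names_to = "feature",
                            values_to = "feature_value")
  dplyr::left_join(long, fl, by = c(".row", "feature")) |>
    dplyr::rename(segment = ".row")
}
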