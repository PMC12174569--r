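# Shapley-value feature attribution for the fitted tree ensemble. Values are
# exact tree-path Shapley attributions in the model's margin (log-odds)
# space, where additivity is exact: base + sum(attributions) = margin output.

#' Shapley attributions for segments
#'
#' Computes per-segment, per-feature Shapley values of the fitted boosted-tree
#' ensemble (exact tree-path algorithm) in margin space, together with the
#' base (expected) value. Positive values push the prediction toward the OL
#' class.
#'
#' @param bundle A `model_bundle`.
#' @param feature_table Feature tibble of the segments to explain.
#' @return An object of class `attribution_table`: list with `shap` (tibble of
#'   per-feature attributions), `base` (scalar base value), `margin`
#'   (per-segment margin output), `features` (the normalised feature values
#'   used), and `provenance` (ids of each row).
#' @export
attribute_segments <- function(bundle, feature_table) {
  missing <- setdiff(bundle$features, names(feature_table))
  if (length(missing) > 0) {
    stop(sprintf("feature table lacks model feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- apply_zscore(bundle$normaliser, feature_table)
  dm <- xgboost::xgb.DMatrix(X)
  contrib <- stats::predict(bundle$booster, dm, predcontrib = TRUE)
  margin <- stats::predict(bundle$booster, dm, outputmargin = TRUE)
  nfeat <- ncol(X)
  shap <- contrib[, seq_len(nfeat), drop = FALSE]
  colnames(shap) <- colnames(X)
  base <- contrib[1, nfeat + 1L]
  prov <- feature_table[, intersect(c("trial_id", "track_id", "segment_index",
                                      "start_s", "net_type"),
                                    names(feature_table))]
  structure(
    list(shap = tibble::as_tibble(shap), base = base, margin = margin,
         features = tibble::as_tibble(X), provenance = tibble::as_tibble(prov)),
    class = "attribution_table"
  )
}

#' Rank features by mean absolute attribution
#'
#' Features are sorted by the mean absolute Shapley value over all explained
#' segments (descending; ties lexicographic). The `direction` column records
#' the sign of the Spearman correlation between feature values and their
#' attributions: +1 means high feature values push toward OL.
#'
#' @param attribution An `attribution_table` from [attribute_segments()].
#' @return A tibble with `feature`, `mean_abs_shap`, `direction`, `rank`.
#' @export
rank_features <- function(attribution) {
  if (!inherits(attribution, "attribution_table")) {
    stop("`attribution` must be an `attribution_table`", call. = FALSE)
  }
  shap <- attribution$shap
  if (nrow(shap) == 0) stop("attribution table is empty", call. = FALSE)
  feats <- attribution$features
  out <- purrr::map(names(shap), function(f) {
    s <- shap[[f]]
    v <- feats[[f]]
    dir <- if (stats::sd(s) == 0 || stats::sd(v) == 0) 0 else
      sign(suppressWarnings(stats::cor(v, s, method = "spearman")))
    tibble::tibble(feature = f, mean_abs_shap = mean(abs(s)),
                   direction = ifelse(is.na(dir), 0, dir))
  }) |> dplyr::bind_rows()
  out <- out[order(-out$mean_abs_shap, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
print.attribution_table <- function(x, ...) {
  cat("<attribution_table>\n")
  cat(sprintf("  segments: %d, features: %d, base value: %.4f\n",
              nrow(x$shap), ncol(x$shap), x$base))
  invisible(x)
}
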