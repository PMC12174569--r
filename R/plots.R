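# ggplot2 graphics for study reports and attributions.

#' Plot the fold-averaged normalised confusion matrix
#'
#' @param report A `study_report`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  m <- report$confusion
  df <- tidyr::expand_grid(true = rownames(m), predicted = colnames(m))
  df$proportion <- mapply(function(t, p) m[t, p], df$true, df$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$proportion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = "Confusion matrix (normalised by true class)") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved accuracy
#'
#' Mean accuracy per 5-min start-time bin across folds, with a standard
#' deviation ribbon; empty bins are gaps, not zeros.
#'
#' @param report A `study_report`.
#' @return A ggplot object.
#' @export
plot_time_accuracy <- function(report) {
  tb <- report$time_accuracy$time_bins
  tb <- tb[!is.na(tb$mean_accuracy), , drop = FALSE]
  tb$mid <- (tb$bin_start_s + tb$bin_end_s) / 2 / 60
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$mid, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_accuracy - .data$sd_accuracy),
      ymax = pmin(1, .data$mean_accuracy + .data$sd_accuracy)),
      alpha = 0.25, fill = "steelblue", na.rm = TRUE) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Track start time (min)", y = "Mean accuracy",
                  title = "Time-resolved track accuracy across folds") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot Shapley feature importance
#'
#' Bar plot of the mean absolute Shapley value per feature for the best
#' fold's attributions, ranked descending.
#'
#' @param report A `study_report`.
#' @param top_n Number of features to show (default 10).
#' @return A ggplot object.
#' @export
plot_shap_importance <- function(report, top_n = 10) {
  imp <- utils::head(report$importance, top_n)
  imp$feature <- stats::reorder(imp$feature, imp$mean_abs_shap)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$mean_abs_shap,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean |SHAP value| (log-odds)", y = NULL,
                  title = sprintf("Feature importance, best fold (%d)",
                                  report$best_fold)) +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' @param object A `study_report`.
#' @param type One of `"confusion"`, `"time"`, `"importance"`.
#' @param ... Passed on to the specific plot function.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object,
                                  type = c("confusion", "time", "importance"),
                                  ...) {
  switch(match.arg(type),
         confusion = plot_confusion(object),
         time = plot_time_accuracy(object),
         importance = plot_shap_importance(object, ...))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
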