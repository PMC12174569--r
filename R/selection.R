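#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value uses
#' exact enumeration of all rank splits when `min(n, m) <= 8`, and otherwise a
#' normal approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @return A list with `statistic` (U for sample `a`), `p_value`, `method`
#'   (`"exact"` or `"normal"`) and `degenerate` (`TRUE` when every value in
#'   both groups is identical, in which case `p_value` is 1).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a); m <- length(b)
  if (n < 1 || m < 1) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = n * m / 2, p_value = 1, log_p = 0,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (min(n, m) <= 8) {
    # exact: enumerate all C(n+m, n) assignments of the observed pooled ranks
    idx <- utils::combn(n + m, n)
    us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    centre <- n * m / 2
    eps <- 1e-9
    p <- mean(abs(us - centre) >= abs(u - centre) - eps)
    log_p <- log(p)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tie_term)
    z <- (abs(u - n * m / 2) - 0.5) / sqrt(v)
    z <- max(z, 0)
    # log-scale p survives underflow, keeping feature ordering strict even
    # for extreme separations
    log_p <- min(0, log(2) + stats::pnorm(-z, log.p = TRUE))
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  list(statistic = u, p_value = p, log_p = log_p, method = method,
       degenerate = FALSE)
}

#' Bonferroni family-wise selection
#'
#' Selects feature `i` iff `p_i <= alpha / m` where `m` is the number of
#' tested features, controlling the family-wise error rate at `alpha`.
#'
#' @param p_values Named numeric vector of raw p-values.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Character vector of selected feature names (or indices when
#'   unnamed).
#' @export
fwer_select <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m < 1) stop("at least one p-value required", call. = FALSE)
  sel <- which(p_values <= alpha / m)
  if (!is.null(names(p_values))) names(p_values)[sel] else sel
}

#' Spearman-correlation deduplication of selected features
#'
#' Computes Spearman correlations between all selected features, then walks
#' the pairs with `|rho|` above the threshold in decreasing `|rho|` order,
#' dropping from each still-intact pair the member with the larger
#' Mann-Whitney p-value (ties: the lexicographically later name). Constant
#' features yield undefined correlations, treated as 0 with a warning.
#'
#' @param feature_table Data frame holding the feature columns.
#' @param selected Character vector of selected feature names.
#' @param rho_threshold Correlation threshold (default 0.85).
#' @param p_values Named p-values used to decide which member to drop.
#' @return A list with `kept` (final feature names), and `dropped` (tibble of
#'   dropped features with the pair correlation that removed them).
#' @export
correlation_dedup <- function(feature_table, selected, rho_threshold = 0.85,
                              p_values = NULL) {
  if (length(selected) == 0) stop("`selected` must be non-empty", call. = FALSE)
  if (length(selected) == 1) {
    return(list(kept = selected,
                dropped = tibble::tibble(feature = character(),
                                         against = character(),
                                         rho = numeric())))
  }
  X <- as.matrix(feature_table[, selected, drop = FALSE])
  if (any(apply(X, 2, function(v) length(unique(v[!is.na(v)])) <= 1))) {
    warning("constant feature(s) present; their correlations are treated as 0",
            call. = FALSE)
  }
  suppressWarnings(rho <- stats::cor(X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[!is.finite(rho)] <- 0

  pairs <- which(upper.tri(rho) & abs(rho) > rho_threshold, arr.ind = TRUE)
  dropped <- tibble::tibble(feature = character(), against = character(),
                            rho = numeric())
  if (nrow(pairs) > 0) {
    ord <- order(-abs(rho[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    alive <- stats::setNames(rep(TRUE, length(selected)), selected)
    for (k in seq_len(nrow(pairs))) {
      f1 <- selected[pairs[k, 1]]; f2 <- selected[pairs[k, 2]]
      if (!alive[f1] || !alive[f2]) next
      p1 <- if (!is.null(p_values)) p_values[[f1]] else NA_real_
      p2 <- if (!is.null(p_values)) p_values[[f2]] else NA_real_
      drop <- if (is.na(p1) || is.na(p2) || p1 == p2) {
        max(f1, f2)  # lexicographically later
      } else if (p1 > p2) f1 else f2
      keep <- setdiff(c(f1, f2), drop)
      alive[drop] <- FALSE
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        feature = drop, against = keep, rho = rho[pairs[k, 1], pairs[k, 2]]))
    }
    selected <- selected[alive[selected]]
  }
  list(kept = selected, dropped = dropped)
}

#' Screen and deduplicate flight features
#'
#' Runs the full selection stage on a feature table: per-feature two-sided
#' Mann-Whitney U tests between the two classes, Bonferroni selection at
#' family-wise error rate `alpha`, then Spearman deduplication at
#' `rho_threshold`.
#'
#' @param feature_table Feature tibble (provenance columns ignored).
#' @param labels Class label per row (two classes).
#' @param alpha Family-wise error rate (default 0.05).
#' @param rho_threshold Spearman threshold (default 0.85).
#' @return An object of class `selection_report`: list with `table`
#'   (per-feature U, p, decisions), `dropped` (dedup record) and `features`
#'   (final list).
#' @export
select_features <- function(feature_table, labels, alpha = 0.05,
                            rho_threshold = 0.85) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) {
    stop("`labels` must contain exactly two classes", call. = FALSE)
  }
  fcols <- feature_columns(feature_table)
  if (length(fcols) == 0) stop("no feature columns found", call. = FALSE)

  tests <- purrr::map(fcols, function(f) {
    v <- feature_table[[f]]
    mw <- mann_whitney_u(v[labels == classes[1]], v[labels == classes[2]])
    tibble::tibble(feature = f, U = mw$statistic, p_value = mw$p_value,
                   log_p = mw$log_p, degenerate = mw$degenerate)
  }) |> dplyr::bind_rows()

  p <- stats::setNames(tests$p_value, tests$feature)
  # dedup compares evidence on the log scale so extreme p-values stay ordered
  logp <- stats::setNames(tests$log_p, tests$feature)
  passed <- fwer_select(p, alpha = alpha)
  tests$selected_fwer <- tests$feature %in% passed
  if (length(passed) == 0) {
    return(structure(list(table = tests,
                          dropped = tibble::tibble(feature = character(),
                                                   against = character(),
                                                   rho = numeric()),
                          features = character(),
                          alpha = alpha, rho_threshold = rho_threshold),
                     class = "selection_report"))
  }
  dd <- correlation_dedup(feature_table, passed, rho_threshold = rho_threshold,
                          p_values = logp)
  tests$kept <- tests$feature %in% dd$kept
  structure(
    list(table = tests, dropped = dd$dropped, features = dd$kept,
         alpha = alpha, rho_threshold = rho_threshold),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat(sprintf("  tested: %d features; FWER-selected: %d; kept after dedup: %d\n",
              nrow(x$table), sum(x$table$selected_fwer), length(x$features)))
  invisible(x)
}
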