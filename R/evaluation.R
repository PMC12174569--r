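# Trial-level cross-validation folds, the metric panel, normalised confusion
# matrices and time-resolved accuracy.

sorted_key <- function(ids) paste(sort(ids), collapse = "|")

# Enumerate or sample the distinct balanced test sets for the per-strain
# composition, then complete each fold with a (strain-balanced) training set.
build_one_test_set <- function(by_cell, strains, ut_per_strain, ol_per_strain,
                               n_test) {
  test <- character()
  ut_slots <- character()
  for (s in strains) {
    ut_pool <- by_cell[[paste(s, "UT")]]
    ol_pool <- by_cell[[paste(s, "OL")]]
    ut_pick <- ut_pool[sample.int(length(ut_pool), ut_per_strain)]
    ol_pick <- ol_pool[sample.int(length(ol_pool), ol_per_strain)]
    test <- c(test, ut_pick, ol_pick)
    ut_slots <- c(ut_slots, ut_pick)
  }
  surplus <- length(test) - n_test
  if (surplus > 0) {
    drop <- ut_slots[sample.int(length(ut_slots), surplus)]
    test <- setdiff(test, drop)
  }
  test
}

#' Generate trial-level cross-validation folds
#'
#' Each fold is a disjoint train/test split of whole trials. Test sets honour
#' a per-strain composition (default: 1 UT and 2 OL trials per strain,
#' surplus UT slots dropped at random down to `n_test`); distinct test sets
#' are sampled without replacement. The remaining trials form the training
#' set, subsampled to `n_train` with class proportions preserved when there
#' are more. With `ut_per_strain = NULL` the composition is ignored and test
#' sets are stratified by net type only.
#'
#' @param trials Trial metadata tibble (`trial_id`, `net_type`, `strain`,
#'   `resistance`).
#' @param n_folds Number of folds to emit (default 30; capped at the number
#'   of distinct test sets, with a warning).
#' @param n_train,n_test Trials per training and test set (defaults 12, 9).
#' @param ut_per_strain,ol_per_strain Test-set composition per strain
#'   (defaults 1, 2), or `NULL` for class-stratified test sets.
#' @param seed Integer seed.
#' @param max_tries Sampling attempts when searching for distinct test sets.
#' @return A tibble with columns `fold`, `train_trials` and `test_trials`
#'   (list-columns of trial ids).
#' @export
generate_folds <- function(trials, n_folds = 30, n_train = 12, n_test = 9,
                           ut_per_strain = 1, ol_per_strain = 2, seed = 1L,
                           max_tries = 5000) {
  trials <- tibble::as_tibble(trials)
  if (length(unique(trials$net_type)) < 2) {
    stop("trial metadata must contain both net types", call. = FALSE)
  }
  composition <- !is.null(ut_per_strain) && !is.null(ol_per_strain)

  local_seed(seed, {
    test_sets <- list()
    seen <- character()
    if (composition) {
      strains <- sort(unique(trials$strain))
      by_cell <- list()
      for (s in strains) {
        for (nt in c("UT", "OL")) {
          pool <- trials$trial_id[trials$strain == s & trials$net_type == nt]
          need <- if (nt == "UT") ut_per_strain else ol_per_strain
          if (length(pool) < need) {
            stop(sprintf("composition unsatisfiable: strain %s has %d %s trial(s), needs %d",
                         s, length(pool), nt, need), call. = FALSE)
          }
          by_cell[[paste(s, nt)]] <- pool
        }
      }
      slots <- length(strains) * (ut_per_strain + ol_per_strain)
      if (slots < n_test) {
        stop(sprintf("composition yields %d test slots but n_test = %d",
                     slots, n_test), call. = FALSE)
      }
      for (try in seq_len(max_tries)) {
        if (length(test_sets) >= n_folds) break
        ts <- build_one_test_set(by_cell, strains, ut_per_strain,
                                 ol_per_strain, n_test)
        key <- sorted_key(ts)
        if (!key %in% seen) {
          seen <- c(seen, key)
          test_sets[[length(test_sets) + 1L]] <- ts
        }
      }
    } else {
      # stratify by net type and resistance when all four cells are populated,
      # otherwise by net type only
      use_res <- "resistance" %in% names(trials) &&
        all(table(trials$net_type, trials$resistance) > 0) &&
        length(unique(trials$resistance)) == 2 && n_test >= 4
      strata_key <- if (use_res) paste(trials$net_type, trials$resistance)
        else trials$net_type
      pools <- split(trials$trial_id, strata_key)
      sizes <- lengths(pools)
      # proportional largest-remainder allocation of n_test over strata,
      # at least one per stratum
      raw <- n_test * sizes / sum(sizes)
      alloc <- pmax(1L, floor(raw))
      while (sum(alloc) > n_test) {
        i <- which.max(alloc)  # shrink the largest
        alloc[i] <- alloc[i] - 1L
      }
      while (sum(alloc) < n_test) {
        rem <- raw - alloc
        i <- which.max(rem)
        alloc[i] <- alloc[i] + 1L
      }
      if (any(alloc > sizes) || any(alloc < 1L)) {
        stop("not enough trials per class for the requested test size", call. = FALSE)
      }
      for (try in seq_len(max_tries)) {
        if (length(test_sets) >= n_folds) break
        ts <- unlist(purrr::map2(pools, alloc, function(pool, k) {
          pool[sample.int(length(pool), k)]
        }), use.names = FALSE)
        key <- sorted_key(ts)
        if (!key %in% seen) {
          seen <- c(seen, key)
          test_sets[[length(test_sets) + 1L]] <- ts
        }
      }
    }
    if (length(test_sets) < n_folds) {
      warning(sprintf("only %d distinct test set(s) found; n_folds capped",
                      length(test_sets)), call. = FALSE)
    }

    folds <- purrr::imap(test_sets, function(ts, i) {
      remaining <- setdiff(trials$trial_id, ts)
      rem <- trials[trials$trial_id %in% remaining, , drop = FALSE]
      if (length(unique(rem$net_type)) < 2) {
        stop("training set would contain a single class", call. = FALSE)
      }
      if (nrow(rem) > n_train) {
        # preserve class proportions, at least one of each
        n_ol_tr <- max(1L, min(n_train - 1L,
                               round(n_train * sum(rem$net_type == "OL") / nrow(rem))))
        n_ut_tr <- n_train - n_ol_tr
        ol_pool <- rem$trial_id[rem$net_type == "OL"]
        ut_pool <- rem$trial_id[rem$net_type == "UT"]
        train <- c(ut_pool[sample.int(length(ut_pool), min(n_ut_tr, length(ut_pool)))],
                   ol_pool[sample.int(length(ol_pool), min(n_ol_tr, length(ol_pool)))])
      } else {
        train <- rem$trial_id
      }
      stopifnot(length(intersect(train, ts)) == 0)
      tibble::tibble(fold = i, train_trials = list(sort(train)),
                     test_trials = list(sort(ts)))
    })
    dplyr::bind_rows(folds)
  })
}

clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

roc_auc_score <- function(scores, truth_pos) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise PR AUC) for the given positive class.
pr_auc_score <- function(scores, truth_pos) {
  if (!any(truth_pos) || all(truth_pos)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  truth_pos <- truth_pos[ord]
  scores <- scores[ord]
  tp <- cumsum(truth_pos)
  fp <- cumsum(!truth_pos)
  last <- !duplicated(scores, fromLast = TRUE)  # threshold boundaries
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(truth_pos)
  sum(diff(c(0, recall)) * precision)
}

prf_scores <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Compute the track-level metric panel
#'
#' Balanced accuracy, ROC AUC (from track scores), Matthews correlation,
#' log loss, Cohen's kappa, and F1/precision/recall/PR AUC computed twice --
#' once with OL and once with UT as the positive class.
#'
#' @param calls Predicted classes (`"UT"`/`"OL"`), one per track.
#' @param scores OL probability scores, one per track.
#' @param truth True classes; both classes must be present (AUCs are `NA`
#'   otherwise).
#' @return A one-row tibble of the panel.
#' @export
compute_metrics <- function(calls, scores, truth) {
  if (length(calls) != length(truth) || length(scores) != length(truth)) {
    stop("`calls`, `scores` and `truth` must have equal length", call. = FALSE)
  }
  truth_ol <- truth == "OL"
  pred_ol <- calls == "OL"
  ol <- prf_scores(pred_ol, truth_ol)
  ut <- prf_scores(!pred_ol, !truth_ol)
  po <- mean(pred_ol == truth_ol)
  pe <- mean(pred_ol) * mean(truth_ol) + mean(!pred_ol) * mean(!truth_ol)
  kappa <- if (1 - pe == 0) 0 else (po - pe) / (1 - pe)
  y <- as.numeric(truth_ol)
  p <- clip_prob(scores)
  tibble::tibble(
    balanced_accuracy = (ol[["recall"]] + ut[["recall"]]) / 2,
    roc_auc = roc_auc_score(scores, truth_ol),
    mcc = mcc_binary(pred_ol, truth_ol),
    log_loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
    cohen_kappa = kappa,
    f1_ol = ol[["f1"]], f1_ut = ut[["f1"]],
    precision_ol = ol[["precision"]], precision_ut = ut[["precision"]],
    recall_ol = ol[["recall"]], recall_ut = ut[["recall"]],
    pr_auc_ol = pr_auc_score(scores, truth_ol),
    pr_auc_ut = pr_auc_score(1 - scores, !truth_ol)
  )
}

#' True-class-normalised confusion matrix
#'
#' Rows are true classes (UT then OL), normalised to sum to 1. When a `fold`
#' vector is given, per-fold matrices are averaged elementwise.
#'
#' @param calls Predicted classes.
#' @param truth True classes (both present).
#' @param fold Optional fold id per prediction.
#' @return A 2x2 matrix with rows `UT`, `OL` (true) and columns `UT`, `OL`
#'   (predicted); each row sums to 1.
#' @export
confusion_normalized <- function(calls, truth, fold = NULL) {
  one <- function(calls, truth) {
    m <- matrix(0, 2, 2, dimnames = list(true = c("UT", "OL"),
                                         predicted = c("UT", "OL")))
    for (cls in c("UT", "OL")) {
      rows <- truth == cls
      if (any(rows)) {
        m[cls, "UT"] <- mean(calls[rows] == "UT")
        m[cls, "OL"] <- mean(calls[rows] == "OL")
      } else {
        m[cls, ] <- NA_real_
      }
    }
    m
  }
  if (is.null(fold)) return(one(calls, truth))
  mats <- lapply(split(seq_along(calls), fold),
                 function(i) one(calls[i], truth[i]))
  Reduce(`+`, mats) / length(mats)
}

#' Time-resolved classification accuracy
#'
#' Bins tracks by start time into half-open `[0, bin_s)`, `[bin_s, 2 bin_s)`,
#' ... windows; within each fold the accuracy over tracks starting in the bin
#' is computed, then the across-fold mean and standard deviation are
#' reported. Empty bins are reported as missing (`NA`), not zero. Companion
#' panels give per-strain, per-class and before/after-cutoff accuracies.
#'
#' @param predictions Tibble of track predictions with columns `fold`,
#'   `start_s`, `track_call`, `net_type` and optionally `strain`.
#' @param bin_s Bin width in seconds (default 300).
#' @param duration_s Trial duration (default 7200); defines the bin range.
#' @param cutoff_s Boundary for the before/after panel (default 1800,
#'   inclusive on the left).
#' @return A list of tibbles: `time_bins`, `by_strain`, `by_class`,
#'   `by_period`.
#' @export
time_resolved_accuracy <- function(predictions, bin_s = 300, duration_s = 7200,
                                   cutoff_s = 1800) {
  stopifnot(all(c("fold", "start_s", "track_call", "net_type") %in%
                  names(predictions)))
  pr <- predictions
  pr$correct <- pr$track_call == pr$net_type
  edges <- seq(0, duration_s, by = bin_s)
  if (edges[length(edges)] < duration_s) edges <- c(edges, duration_s)
  pr$bin <- findInterval(pr$start_s, edges, rightmost.closed = FALSE)

  per_fold <- pr |>
    dplyr::group_by(.data$bin, .data$fold) |>
    dplyr::summarise(acc = mean(.data$correct), n = dplyr::n(), .groups = "drop")
  all_bins <- tibble::tibble(bin = seq_len(length(edges) - 1))
  time_bins <- all_bins |>
    dplyr::left_join(per_fold, by = "bin") |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_tracks = sum(.data$n, na.rm = TRUE),
      mean_accuracy = if (all(is.na(.data$acc))) NA_real_ else
        mean(.data$acc, na.rm = TRUE),
      sd_accuracy = if (sum(!is.na(.data$acc)) < 2) NA_real_ else
        stats::sd(.data$acc, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_start_s = edges[.data$bin],
                  bin_end_s = edges[.data$bin + 1L], .before = 1) |>
    dplyr::select(-"bin")

  panel <- function(df, group) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group)), .data$fold) |>
      dplyr::summarise(acc = mean(.data$correct), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::summarise(n_tracks = sum(.data$n),
                       mean_accuracy = mean(.data$acc),
                       sd_accuracy = if (dplyr::n() < 2) NA_real_ else
                         stats::sd(.data$acc),
                       .groups = "drop")
  }
  pr$period <- ifelse(pr$start_s <= cutoff_s, "first_30min", "after_30min")
  list(
    time_bins = time_bins,
    by_strain = if ("strain" %in% names(pr)) panel(pr, "strain") else NULL,
    by_class = panel(pr, "net_type"),
    by_period = panel(pr, "period")
  )
}
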