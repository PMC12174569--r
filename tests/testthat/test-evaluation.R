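# Fold generation, the metric panel, confusion matrices and time-resolved
# accuracy.

paper_style_trials <- function(n_ut_per_strain = 2, n_ol_per_strain = 3) {
  strains <- c("Banfora", "Kisumu", "NGousso", "VK7")
  dplyr::bind_rows(
    tidyr::expand_grid(strain = strains, rep = seq_len(n_ut_per_strain)) |>
      dplyr::mutate(net_type = "UT"),
    tidyr::expand_grid(strain = strains, rep = seq_len(n_ol_per_strain)) |>
      dplyr::mutate(net_type = "OL")
  ) |>
    dplyr::mutate(
      trial_id = sprintf("%s_%s_%d", net_type, strain, rep),
      resistance = ifelse(strain %in% c("Banfora", "VK7"), "IR", "IS")
    ) |>
    dplyr::select(trial_id, net_type, strain, resistance)
}

test_that("fold composition combinatorics behave as forced", {
  # only 4 distinct class-stratified test sets exist: folds are capped
  trials <- paper_style_trials(2, 2)[c(1, 2, 9, 10), ]
  expect_warning(
    folds <- generate_folds(trials, n_folds = 10, n_train = 2, n_test = 2,
                            ut_per_strain = NULL, ol_per_strain = NULL,
                            seed = 2),
    "capped")
  expect_equal(nrow(folds), 4)

  # per-strain composition: 1 UT of 2 and 2 OL of 3 per strain gives
  # (2 * 3)^4 distinct test sets; 30 sampled without replacement
  trials2 <- paper_style_trials(2, 3)
  folds2 <- generate_folds(trials2, n_folds = 30, n_train = 6, n_test = 12,
                           ut_per_strain = 1, ol_per_strain = 2, seed = 2)
  expect_equal(nrow(folds2), 30)
  keys <- vapply(folds2$test_trials, function(x) paste(sort(x), collapse = "|"),
                 character(1))
  expect_false(any(duplicated(keys)))
  # every test set honours the composition
  for (ts in folds2$test_trials) {
    sub <- trials2[match(ts, trials2$trial_id), ]
    comp <- table(sub$strain, sub$net_type)
    expect_true(all(comp[, "UT"] == 1))
    expect_true(all(comp[, "OL"] == 2))
  }
})

test_that("folds are trial-disjoint with both classes on both sides", {
  trials <- paper_style_trials(2, 3)
  folds <- generate_folds(trials, n_folds = 30, n_train = 11, n_test = 9,
                          ut_per_strain = 1, ol_per_strain = 2, seed = 7)
  expect_equal(nrow(folds), 30)
  for (i in seq_len(nrow(folds))) {
    train <- folds$train_trials[[i]]
    test <- folds$test_trials[[i]]
    expect_length(intersect(train, test), 0)
    expect_length(test, 9)
    expect_lte(length(train), 11)
    nt <- trials$net_type[match(c(train, test), trials$trial_id)]
    expect_setequal(unique(nt[seq_along(train)]), c("UT", "OL"))
    expect_setequal(unique(nt[-seq_along(train)]), c("UT", "OL"))
  }
  # deterministic under seed
  folds_again <- generate_folds(trials, n_folds = 30, n_train = 11, n_test = 9,
                                ut_per_strain = 1, ol_per_strain = 2, seed = 7)
  expect_identical(folds, folds_again)
  expect_error(
    generate_folds(trials, n_folds = 2, n_train = 4, n_test = 9,
                   ut_per_strain = 3, ol_per_strain = 2, seed = 1),
    "composition unsatisfiable.*UT")
})

test_that("the metric panel reproduces closed-form cases", {
  # confusion TP=8 FN=2 TN=9 FP=1 with OL positive
  truth <- c(rep("OL", 10), rep("UT", 10))
  calls <- c(rep("OL", 8), rep("UT", 2), rep("OL", 1), rep("UT", 9))
  scores <- ifelse(calls == "OL", 0.9, 0.1)
  m <- compute_metrics(calls, scores, truth)
  expect_equal(m$balanced_accuracy, (0.8 + 0.9) / 2)
  expect_equal(m$recall_ol, 0.8)
  expect_equal(m$recall_ut, 0.9)
  expect_equal(m$precision_ol, 8 / 9)

  perfect <- compute_metrics(truth, ifelse(truth == "OL", 1, 0), truth)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$cohen_kappa, 1)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$pr_auc_ol, 1)
  expect_equal(perfect$pr_auc_ut, 1)
  expect_lt(perfect$log_loss, 1e-10)

  all_ol <- compute_metrics(rep("OL", 20), rep(0.7, 20), truth)
  expect_equal(all_ol$recall_ol, 1)
  expect_equal(all_ol$balanced_accuracy, 0.5)
  expect_equal(all_ol$mcc, 0)
})

test_that("every panel member matches the naive oracle on random inputs", {
  set.seed(60)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    truth <- ifelse(runif(n) < 0.5, "OL", "UT")
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)  # ties included
    calls <- ifelse(scores >= runif(1), "OL", "UT")
    fast <- compute_metrics(calls, scores, truth)
    slow <- naive_metrics(calls, scores, truth)
    expect_equal(unlist(fast), slow, tolerance = 1e-9)
  }
})

test_that("normalised confusion matrices have unit rows and average over folds", {
  truth <- c("UT", "UT", "OL", "OL", "OL")
  calls <- c("UT", "OL", "OL", "OL", "UT")
  m <- confusion_normalized(calls, truth)
  expect_equal(rowSums(m), c(UT = 1, OL = 1))
  expect_equal(m["OL", "OL"], 2 / 3)

  perfect <- confusion_normalized(truth, truth)
  expect_equal(unname(perfect), diag(2))

  set.seed(31)
  truth_big <- rep(c("UT", "OL"), each = 2000)
  coin <- ifelse(runif(4000) < 0.5, "OL", "UT")
  mc <- confusion_normalized(coin, truth_big)
  expect_true(all(abs(mc - 0.5) < 3 * sqrt(0.25 / 2000)))

  folded <- confusion_normalized(c(calls, truth), c(truth, truth),
                                 fold = rep(1:2, each = 5))
  expect_equal(rowSums(folded), c(UT = 1, OL = 1))
  expect_equal(folded["OL", "OL"], (2 / 3 + 1) / 2)
})

test_that("time-resolved accuracy bins half-open and reports empty bins as NA", {
  preds <- tibble::tibble(
    fold = rep(1:2, each = 3),
    start_s = rep(c(10, 304.9, 700), 2),
    net_type = rep(c("OL", "UT", "OL"), 2),
    track_call = c("OL", "UT", "OL", "OL", "OT", "UT"),
    strain = "Kisumu"
  )
  preds$track_call[5] <- "OL"  # wrong in fold 2 bin 2
  ta <- time_resolved_accuracy(preds, bin_s = 300, duration_s = 1200)
  tb <- ta$time_bins
  expect_equal(nrow(tb), 4)
  expect_equal(tb$bin_start_s, c(0, 300, 600, 900))
  # 304.9 falls in [300, 600)
  expect_equal(tb$n_tracks[2], 2)
  expect_equal(tb$mean_accuracy[2], 0.5)
  expect_true(is.na(tb$mean_accuracy[4]))
  expect_equal(tb$n_tracks[4], 0)
  # per-class and before/after panels exist
  expect_true(all(c("net_type", "mean_accuracy") %in% names(ta$by_class)))
  expect_true(all(ta$by_period$period %in% c("first_30min", "after_30min")))
})

test_that("perfect predictions give unit accuracy in every populated bin", {
  preds <- tibble::tibble(
    fold = 1, start_s = c(0, 299, 300, 3000), net_type = "UT",
    track_call = "UT", strain = "S")
  ta <- time_resolved_accuracy(preds, bin_s = 300, duration_s = 7200)
  filled <- !is.na(ta$time_bins$mean_accuracy)
  expect_true(all(ta$time_bins$mean_accuracy[filled] == 1))
  expect_equal(sum(ta$time_bins$n_tracks), 4)
})
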