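# Training-set strategies, normalisation, classifier training,
# decision-boundary tuning and track-level aggregation.

fake_table <- function(counts, segments_per_track = 2) {
  rows <- list()
  id <- 0
  for (nm in names(counts)) {
    parts <- strsplit(nm, "/")[[1]]
    for (k in seq_len(counts[[nm]])) {
      id <- id + 1
      rows[[id]] <- tibble::tibble(
        trial_id = paste0(parts[1], "_tr"), track_id = sprintf("t%04d", id),
        segment_index = seq_len(segments_per_track),
        start_s = ifelse(k %% 2 == 0, 100, 2500),
        quality = 0, net_type = parts[1], strain = "S", resistance = parts[2],
        f = stats::rnorm(segments_per_track)
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the balanced strategy equalises track counts on the OL/IS reference", {
  set.seed(1)
  ft <- fake_table(c("OL/IS" = 6, "OL/IR" = 20, "UT/IS" = 30, "UT/IR" = 40))
  # only OL/IS tracks starting within 30 min anchor the subsampling
  n_ref <- nrow(dplyr::distinct(
    dplyr::filter(ft, net_type == "OL", resistance == "IS", start_s <= 1800),
    trial_id, track_id))
  out <- build_training_set(ft, "balanced", seed = 5)
  counts <- out |>
    dplyr::distinct(trial_id, track_id, net_type, resistance) |>
    dplyr::count(net_type, resistance)
  expect_true(all(counts$n == n_ref))
  # segments follow their tracks
  expect_true(all(table(paste(out$trial_id, out$track_id)) == 2))
  # reproducible under seed
  expect_identical(out, build_training_set(ft, "balanced", seed = 5))
})

test_that("the early strategy keeps the inclusive 30-min boundary", {
  ft <- fake_table(c("OL/IS" = 2, "UT/IR" = 2))
  # one track per group starts at 1799 (kept, inclusive), one at 1801 (dropped)
  ft$start_s <- rep(rep(c(1799, 1801), each = 2), 2)
  out <- build_training_set(ft, "early", seed = 1)
  kept_tracks <- unique(out$track_id)
  starts <- tapply(ft$start_s, ft$track_id, min)
  expect_setequal(kept_tracks, names(starts)[starts <= 1800])
  expect_true(any(out$start_s == 1799))
  full <- build_training_set(ft, "comprehensive", seed = 1)
  expect_equal(nrow(full), nrow(ft))
  ft2 <- dplyr::filter(ft, net_type != "OL")
  expect_error(build_training_set(ft2, "balanced", seed = 1), "OL/IS")
})

test_that("z-score normalisation uses training statistics only", {
  train <- data.frame(a = c(3, 5, 7), b = c(1, 1, 1))
  expect_warning(norm <- fit_zscore(train), "constant")
  out <- apply_zscore(norm, data.frame(a = 9, b = 10))
  expect_equal(unname(out[1, "a"]), (9 - 5) / 2)
  self <- apply_zscore(norm, train)
  expect_equal(colMeans(self), c(a = 0, b = 0))
  expect_equal(unname(self[, "b"]), c(0, 0, 0))
  expect_equal(sd(self[, "a"]), 1)
})

test_that("the boundary sweep maximises MCC with the tie rules", {
  tau <- tune_decision_boundary(c(0.9, 0.8, 0.2, 0.1),
                                c("OL", "OL", "UT", "UT"))
  expect_equal(tau, 0.21)  # smallest grid point of the perfect range
  tau0 <- tune_decision_boundary(c(0.5, 0.5, 0.5, 0.5),
                                 c("OL", "OL", "UT", "UT"))
  expect_equal(tau0, 0.01)
  set.seed(30)
  for (i in 1:100) {
    probs <- runif(40)
    labels <- ifelse(runif(40) < 0.5, "OL", "UT")
    if (length(unique(labels)) < 2) next
    expect_equal(tune_decision_boundary(probs, labels),
                 naive_boundary_sweep(probs, labels))
  }
})

test_that("the classifier separates a separable toy set and is seeded", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100, 3), 50), matrix(rnorm(100, -3), 50))
  colnames(X) <- c("u", "v")
  labels <- rep(c("OL", "UT"), each = 50)
  b1 <- train_classifier(X, labels, nrounds = 30, seed = 4)
  b2 <- train_classifier(X, labels, nrounds = 30, seed = 4)
  p <- predict(b1, xgboost::xgb.DMatrix(X))
  expect_identical(p, predict(b2, xgboost::xgb.DMatrix(X)))
  calls <- ifelse(p >= 0.5, "OL", "UT")
  expect_equal(mean(calls == labels), 1)
  expect_error(train_classifier(X, rep("OL", 100)), "both classes")
  expect_equal(attr(b1, "class_weight"), 1)
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(44)
  X <- matrix(rnorm(400 * 5), 400, 5, dimnames = list(NULL, paste0("f", 1:5)))
  labels <- sample(rep(c("OL", "UT"), each = 200))
  accs <- vapply(1:4, function(f) {
    test_idx <- seq((f - 1) * 100 + 1, f * 100)
    b <- train_classifier(X[-test_idx, ], labels[-test_idx], nrounds = 50,
                          seed = f)
    p <- predict(b, xgboost::xgb.DMatrix(X[test_idx, , drop = FALSE]))
    calls <- ifelse(p >= 0.5, "OL", "UT")
    truth <- labels[test_idx]
    mean(c(mean(calls[truth == "OL"] == "OL"),
           mean(calls[truth == "UT"] == "UT")))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("track aggregation uses the mode with the mean-probability tie rule", {
  ft <- tibble::tibble(
    trial_id = "T", track_id = c("a", "a", "a", "b", "b", "c"),
    start_s = 0, net_type = "OL"
  )
  probs <- c(0.9, 0.8, 0.1,  0.9, 0.5,  0.4)
  out <- aggregate_track_predictions(ft, probs, tau = 0.6)
  out <- out[order(out$track_id), ]
  expect_equal(out$track_call, c("OL",  # majority 2/3
                                 "OL",  # 1-1 tie, mean 0.7 >= 0.6
                                 "UT")) # single segment below tau
  expect_equal(out$n_segments, c(3L, 2L, 1L))
  expect_equal(out$track_score, c(mean(c(0.9, 0.8, 0.1)), 0.7, 0.4))

  out2 <- aggregate_track_predictions(ft[4:5, ], probs[4:5], tau = 0.71)
  expect_equal(out2$track_call, "UT")  # tie, mean 0.7 < 0.71
})

test_that("a fitted bundle predicts every track with at least one segment", {
  bundle <- small_bundle()
  ft <- small_feature_table()
  preds <- predict_tracks(bundle, ft)
  n_tracks <- nrow(dplyr::distinct(ft, trial_id, track_id))
  expect_equal(nrow(preds), n_tracks)
  expect_true(all(preds$track_call %in% c("UT", "OL")))
  expect_true(all(preds$n_segments >= 1))
  expect_true(bundle$tau %in% seq(0.01, 0.99, by = 0.01))
  expect_gt(bundle$class_weight, 0)
  expect_error(predict_tracks(bundle, ft[, 1:6]), "lacks model feature")
  imp <- tidy(bundle)
  expect_true(all(imp$feature %in% bundle$features))
})
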