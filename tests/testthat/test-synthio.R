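# Flight simulator: determinism, limiting cases, behavioural monotonicity,
# censoring and gap injection.

test_that("parameter validation rejects malformed behaviour parameters", {
  expect_error(behaviour_params(-1, 10, 1, 0, 0), "mean_speed")
  expect_error(behaviour_params(100, -1, 1, 0, 0), "speed_sd")
  expect_error(behaviour_params(100, 10, -1, 0, 0), "turn_concentration")
  expect_error(behaviour_params(100, 10, 1, -1, 0), "reversal_rate")
  expect_error(behaviour_params(100, 10, 1, 0, 1.5), "pause_prob")
  expect_error(behaviour_params(100, 10, NA, 0, 0), "turn_concentration")
})

test_that("zero-noise limit gives straight flight and zero-speed gives no path", {
  straight <- behaviour_params(300, 0, Inf, 0, 0)
  tr <- simulate_track(straight, duration_s = 5, fps = 50,
                       arena = c(1e6, 1e6), seed = 5)
  f <- extract_segment_features(tr, fps = 50)
  expect_gt(f[["straightness"]], 1 - 1e-9)
  expect_equal(f[["angle_change_max"]], 0, tolerance = 1e-9)

  still <- behaviour_params(0, 0, 1, 0, 0)
  tr0 <- simulate_track(still, duration_s = 2, seed = 5)
  f0 <- extract_segment_features(tr0, fps = 50)
  expect_identical(f0[["path_length"]], 0)
  expect_identical(f0[["straightness"]], 0)
})

test_that("higher turn concentration lowers mean absolute angle change", {
  hi <- behaviour_params(400, 50, 8, 0, 0)
  lo <- behaviour_params(400, 50, 0.5, 0, 0)
  mean_angle <- function(params, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_track(params, duration_s = 4, seed = s)
      extract_segment_features(tr)[["angle_change_mean"]]
    }, numeric(1))
  }
  a_hi <- mean_angle(hi, 1:100)
  a_lo <- mean_angle(lo, 101:200)
  expect_lt(mean(a_hi), mean(a_lo))
})

test_that("higher reversal rate increases horizontal-velocity sign changes", {
  lo <- behaviour_params(400, 50, 4, 0.2, 0)
  hi <- behaviour_params(400, 50, 4, 4, 0)
  crossings_per_s <- function(params, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_track(params, duration_s = 4, seed = s)
      extract_segment_features(tr)[["vx_zero_crossings"]] / 4
    }, numeric(1))
  }
  c_lo <- crossings_per_s(lo, 1:100)
  c_hi <- crossings_per_s(hi, 201:300)
  tt <- t.test(c_hi, c_lo, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("simulated tracks stay inside the arena and are reproducible", {
  params <- ol_flight_params()
  tr1 <- simulate_track(params, duration_s = 30, arena = c(1200, 1000), seed = 99)
  tr2 <- simulate_track(params, duration_s = 30, arena = c(1200, 1000), seed = 99)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$x_mm >= 0 & tr1$x_mm <= 1200))
  expect_true(all(tr1$y_mm >= 0 & tr1$y_mm <= 1000))
  expect_true(all(diff(tr1$frame) == 1L))
  tr3 <- simulate_track(params, duration_s = 30, seed = 100)
  expect_false(identical(tr1$x_mm, tr3$x_mm))
})

test_that("pause frames produce exact zero displacements", {
  params <- behaviour_params(400, 80, 2, 0.5, 0.3, pause_run_mean = 3)
  tr <- simulate_track(params, duration_s = 10, seed = 17)
  dx <- diff(tr$x_mm); dy <- diff(tr$y_mm)
  expect_gt(sum(dx == 0 & dy == 0), 0)
})

test_that("gap injection preserves endpoints, order and the removal rate", {
  params <- ut_flight_params()
  tr <- simulate_track(params, duration_s = 200.04, seed = 31)  # 10002 frames
  expect_identical(inject_gaps(tr, 0, seed = 1), tr)

  gapped <- inject_gaps(tr, 0.1, gap_max_run = 3, seed = 8)
  expect_identical(gapped[1, ], tr[1, ])
  expect_identical(gapped[nrow(gapped), ], tr[nrow(tr), ])
  expect_true(all(diff(gapped$frame) > 0))
  removed <- (nrow(tr) - nrow(gapped)) / (nrow(tr) - 2)
  margin <- 2.576 * sqrt(0.1 * 0.9 / (nrow(tr) - 2))
  expect_lt(abs(removed - 0.1), margin + 0.003)  # small allowance for run capping
  runs <- rle(diff(gapped$frame) > 1)
  expect_true(all(diff(gapped$frame) - 1 <= 3))

  expect_identical(inject_gaps(tr, 0.1, 3, seed = 8), gapped)
})

test_that("trial simulation censors IS mosquitoes at an OL net", {
  spec <- trial_spec("OL01", "OL", "Kisumu", "IS", n_mosquitoes = 20,
                     duration_s = 7200, seed = 12)
  expect_equal(spec$mortality_cutoff_s, 1800)
  tracks <- simulate_trial(spec)
  starts <- tapply(tracks$t_s, tracks$track_id, min)
  expect_true(all(starts <= 1800))
  expect_lte(max(tracks$t_s), 1800 + 0.1)
  # identical spec reruns byte-identically
  expect_identical(tracks, simulate_trial(spec))
  # no cutoff for IR at OL
  spec_ir <- trial_spec("OL02", "OL", "VK7", "IR", seed = 12)
  expect_true(is.na(spec_ir$mortality_cutoff_s))
})

test_that("trial spec rejects inconsistent censoring", {
  expect_error(trial_spec("T", "UT", "Kisumu", "IS", duration_s = 1000,
                          mortality_cutoff_s = 1800), "exceed")
})

test_that("a study emits the requested trials with unique ids and metadata", {
  study <- simulate_study(17, 23, n_mosquitoes = 1, duration_s = 120, seed = 3)
  expect_equal(nrow(study$trials), 40)
  expect_equal(sum(study$trials$net_type == "UT"), 17)
  expect_equal(sum(study$trials$net_type == "OL"), 23)
  expect_false(any(duplicated(study$trials$trial_id)))
  # every strain appears in both arms
  tab <- table(study$trials$net_type, study$trials$strain)
  expect_true(all(tab > 0))

  tiny <- simulate_study(1, 1, n_mosquitoes = 1, duration_s = 60,
                         check_balance = FALSE, seed = 4)
  expect_equal(sort(tiny$trials$net_type), c("OL", "UT"))
  expect_identical(tiny$tracks,
                   simulate_study(1, 1, n_mosquitoes = 1, duration_s = 60,
                                  check_balance = FALSE, seed = 4)$tracks)
  expect_error(simulate_study(2, 4, n_mosquitoes = 1, duration_s = 60, seed = 1),
               "at least one trial per strain")
})
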