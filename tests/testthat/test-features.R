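# Kinematic series, zero-crossing rules, masked summaries and the feature
# vector, cross-checked against naive loop oracles.

seg_from_xy <- function(x, y, real = TRUE) {
  n <- length(x)
  tibble::tibble(trial_id = "T", track_id = "a", frame = seq_len(n) - 1L,
                 t_s = (seq_len(n) - 1L) / 50, x_mm = x, y_mm = y,
                 real_flag = rep_len(real, n))
}

test_that("kinematic series reproduce textbook cases", {
  ks <- kinematic_series(seg_from_xy(c(0, 10, 20), c(0, 0, 0)), fps = 50)
  expect_equal(ks$vx$values, c(500, 500))
  expect_equal(ks$angle_change$values, 0)

  ks2 <- kinematic_series(seg_from_xy(c(0, 10, 10), c(0, 0, 10)), fps = 50)
  expect_equal(ks2$angle_change$values, pi / 2)

  ks3 <- kinematic_series(seg_from_xy(c(0, 10, 0), c(0, 0, 0)), fps = 50)
  expect_equal(ks3$angle_change$values, pi)

  expect_error(kinematic_series(seg_from_xy(c(0, 1), c(0, 0))), "at least 3")
})

test_that("zero-crossing counts follow the signed and unsigned rules", {
  expect_equal(zero_crossings(c(0.5, -0.2, 0.3, 0.0, -0.1), signed = TRUE), 3L)
  expect_equal(zero_crossings(c(0, 0.2, 0, 0), signed = FALSE), 3L)
  expect_equal(zero_crossings(c(1, 1, 1), signed = TRUE), 0L)
  # masked samples break adjacency: the (-1, +1) pair spans a masked sample
  expect_equal(zero_crossings(c(-1, 5, 1), signed = TRUE,
                              mask = c(TRUE, FALSE, TRUE)), 0L)
  expect_equal(zero_crossings(c(-1, 1, 1), signed = TRUE,
                              mask = c(TRUE, TRUE, FALSE)), 1L)
  # tolerance band is configurable
  expect_equal(zero_crossings(c(1e-9, 1, -1), signed = FALSE, tol = 1e-6), 1L)
})

test_that("summaries use interpolation quantiles and honour the mask", {
  s <- summarize_series(c(1, 2, 3, 4))
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["q1"]], 1.75)
  expect_equal(s[["q3"]], 3.25)
  expect_equal(s[["sd"]], sd(1:4))

  s1 <- summarize_series(5)
  expect_equal(s1[["mean"]], 5)
  expect_equal(s1[["min"]], 5)
  expect_true(is.na(s1[["sd"]]))

  sm <- summarize_series(c(1, 2, 3, 100), mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sm[["mean"]], 2)
  expect_equal(sm[["max"]], 3)

  expect_true(all(is.na(summarize_series(c(1, 2), mask = c(FALSE, FALSE)))))
})

test_that("feature vectors capture limiting geometries", {
  straight <- seg_from_xy(seq(0, 100, by = 10), rep(0, 11))
  f <- extract_segment_features(straight, fps = 50)
  expect_equal(f[["straightness"]], 1)
  expect_equal(f[["angle_change_q1"]], 0)
  expect_equal(f[["vx_zero_crossings"]], 0)

  theta <- seq(0, 2 * pi, length.out = 20)
  loop <- seg_from_xy(cos(theta) * 50, sin(theta) * 50)
  fl <- extract_segment_features(loop, fps = 50)
  expect_equal(fl[["net_displacement"]], 0, tolerance = 1e-9)
  expect_equal(fl[["straightness"]], 0, tolerance = 1e-9)
})

test_that("every feature matches the naive loop oracle on random segments", {
  set.seed(99)
  for (i in 1:100) {
    seg <- random_segment(n = sample(10:60, 1), gap = i %% 2 == 0)
    fast <- extract_segment_features(seg, fps = 50)
    slow <- naive_segment_features(seg, fps = 50)
    expect_equal(fast[names(slow)], slow, tolerance = 1e-9)
  }
})

test_that("rotation leaves intrinsic features invariant but not vx/vy", {
  set.seed(5)
  seg <- random_segment(n = 50, gap = TRUE)
  a <- 0.83
  rot <- seg
  rot$x_mm <- cos(a) * seg$x_mm - sin(a) * seg$y_mm
  rot$y_mm <- sin(a) * seg$x_mm + cos(a) * seg$y_mm
  f0 <- extract_segment_features(seg)
  f1 <- extract_segment_features(rot)
  invariant <- c(grep("^(speed|angle_change|curvature)_", names(f0), value = TRUE),
                 "path_length", "net_displacement", "straightness")
  invariant <- setdiff(invariant, "angle_change_zero_crossings")
  expect_equal(f1[invariant], f0[invariant], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1[["vx_mean"]], f0[["vx_mean"]],
                                tolerance = 1e-9)))
})

test_that("scaling doubles lengths and speeds and halves curvature", {
  set.seed(6)
  seg <- random_segment(n = 40, gap = FALSE)
  seg2 <- seg
  seg2$x_mm <- 2 * seg$x_mm
  seg2$y_mm <- 2 * seg$y_mm
  f1 <- extract_segment_features(seg)
  f2 <- extract_segment_features(seg2)
  for (nm in c("speed_mean", "accel_mean", "path_length", "net_displacement")) {
    expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-9)
  }
  expect_equal(f2[["curvature_median"]], f1[["curvature_median"]] / 2,
               tolerance = 1e-9)
  expect_equal(f2[["angle_change_median"]], f1[["angle_change_median"]],
               tolerance = 1e-9)
  expect_equal(f2[["straightness"]], f1[["straightness"]], tolerance = 1e-9)
})

test_that("masking a sample never lets it influence the summaries", {
  set.seed(8)
  seg <- random_segment(n = 30, gap = FALSE)
  seg$x_mm[12] <- 1e6  # wild outlier
  masked <- seg
  masked$real_flag[12] <- FALSE
  f <- extract_segment_features(masked)
  # recompute from scratch with the outlier replaced: summaries of valid
  # samples must be identical because the outlier only touches masked entries
  seg2 <- masked
  seg2$x_mm[12] <- 5e5
  f2 <- extract_segment_features(seg2)
  touched <- setdiff(names(f), c("net_displacement"))
  expect_equal(f[touched], f2[touched], tolerance = 1e-12)
})

test_that("angle change always lies in [0, pi]", {
  set.seed(10)
  for (i in 1:50) {
    seg <- random_segment(n = 25, gap = FALSE)
    ks <- kinematic_series(seg)
    expect_true(all(ks$angle_change$values >= 0))
    expect_true(all(ks$angle_change$values <= pi + 1e-12))
  }
})

test_that("feature tables attach provenance and drop unusable segments", {
  ft <- small_feature_table()
  expect_true(all(c("trial_id", "track_id", "segment_index", "start_s",
                    "quality", "net_type", "strain", "resistance")
                  %in% names(ft)))
  expect_gt(nrow(ft), 10)
  expect_false(any(is.na(as.matrix(ft[, feature_columns(ft)]))))
  # schema is stable across calls
  expect_identical(feature_columns(ft), feature_names_for(FALSE))
  # a fully interpolated segment is dropped with a warning
  tr <- toy_track(0:399, x = (0:399) * 2, y = rep(1, 400), real = FALSE)
  tr$real_flag[c(1, 400)] <- TRUE
  segs <- window_track(tr, 7.5, 7, 50)
  segs$trial_id <- "T1"; segs$track_id <- "a"
  expect_warning(expect_error(build_feature_table(tr, segs), "no usable"),
                 "dropped")
})
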