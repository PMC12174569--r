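# Kinematic and geometric flight features per segment. Statistical summaries
# are computed over real (observed) positions only; interpolated samples are
# masked out of every summary.

# Per-track (or per-segment) kinematic series from position vectors.
# Velocity sample t is valid iff positions t and t+1 are real; angle change,
# acceleration and curvature sample t iff positions t, t+1, t+2 are real.
compute_series <- function(x, y, real, fps) {
  n <- length(x)
  dx <- diff(x)
  dy <- diff(y)
  vx <- dx * fps
  vy <- dy * fps
  speed <- sqrt(vx^2 + vy^2)
  step_len <- speed / fps
  theta <- atan2(vy, vx)
  angle_change <- abs(wrap_angle(diff(theta)))
  accel <- sqrt(diff(vx)^2 + diff(vy)^2) * fps
  curvature <- ifelse(step_len[-(n - 1)] > 0,
                      angle_change / step_len[-(n - 1)], NA_real_)
  valid_v <- real[-n] & real[-1]
  valid_a <- valid_v[-(n - 1)] & real[-c(1, 2)]
  list(
    vx = vx, vy = vy, speed = speed, accel = accel,
    angle_change = angle_change, curvature = curvature,
    step_len = step_len,
    valid_v = valid_v,
    valid_a = valid_a,
    valid_curv = valid_a & step_len[-(n - 1)] > 0
  )
}

#' Kinematic series of one segment
#'
#' First-difference velocities (`vx`, `vy`, mm/s), speed (mm/s), acceleration
#' magnitude (mm/s^2), absolute wrapped heading change (`angle_change`,
#' radians in `[0, pi]`) and curvature (radians/mm, heading change per unit of
#' step path length). Each series carries a validity mask: a velocity sample
#' is valid iff both endpoint positions are real; angle change, acceleration
#' and curvature samples require all three contributing positions to be real
#' (curvature additionally a positive step length).
#'
#' @param segment Data frame of segment samples with `x_mm`, `y_mm`,
#'   `real_flag` (>= 3 rows).
#' @param fps Frames per second.
#' @return A named list of series; each element is a list with `values` and
#'   `valid`.
#' @export
kinematic_series <- function(segment, fps = 50) {
  if (nrow(segment) < 3) stop("segment must have at least 3 samples", call. = FALSE)
  s <- compute_series(segment$x_mm, segment$y_mm, segment$real_flag, fps)
  list(
    vx = list(values = s$vx, valid = s$valid_v),
    vy = list(values = s$vy, valid = s$valid_v),
    speed = list(values = s$speed, valid = s$valid_v),
    accel = list(values = s$accel, valid = s$valid_a),
    angle_change = list(values = s$angle_change, valid = s$valid_a),
    curvature = list(values = s$curvature, valid = s$valid_curv)
  )
}

#' Count zero-crossings of a series
#'
#' Over valid samples only: for a signed series the count is the number of
#' exactly-zero samples plus the number of adjacent valid pairs with strictly
#' opposite signs (no pair spans a masked sample); for a non-negative series
#' it is the number of exactly-zero samples. "Exactly zero" means
#' `abs(x) <= tol` with `tol = 0` by default.
#'
#' @param series Numeric vector.
#' @param signed Logical: is the series signed (sign flips counted)?
#' @param mask Logical validity mask (default: all valid).
#' @param tol Zero tolerance (default 0, exact).
#' @return A non-negative integer count.
#' @export
zero_crossings <- function(series, signed = TRUE, mask = NULL, tol = 0) {
  if (is.null(mask)) mask <- rep(TRUE, length(series))
  zeros <- sum(abs(series[mask]) <= tol, na.rm = TRUE)
  if (!signed) return(as.integer(zeros))
  flips <- 0L
  n <- length(series)
  if (n >= 2) {
    a <- series[-n]; b <- series[-1]
    pair_ok <- mask[-n] & mask[-1] & !is.na(a) & !is.na(b)
    flips <- sum(pair_ok & abs(a) > tol & abs(b) > tol & (a > 0) != (b > 0))
  }
  as.integer(zeros + flips)
}

#' Statistical summary of a series over valid samples
#'
#' Mean, standard deviation (denominator `n - 1`), min, max and the quartiles
#' by linear interpolation of order statistics (the type-7 convention).
#' With no valid samples every summary is `NA`; with one valid sample the sd
#' is `NA`.
#'
#' @param series Numeric vector.
#' @param mask Logical validity mask (default: all valid).
#' @return Named numeric vector `mean`, `sd`, `min`, `max`, `q1`, `median`,
#'   `q3`.
#' @export
summarize_series <- function(series, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(series))
  v <- series[mask & !is.na(series)]
  if (length(v) == 0) {
    return(c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
             q1 = NA_real_, median = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(v),
    sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
    min = min(v), max = max(v),
    q1 = q[1], median = q[2], q3 = q[3])
}

# Which series get a zero-crossing summary, and whether it is signed.
zc_plan <- function(magnitude_zero_crossings = FALSE) {
  plan <- list(vx = TRUE, vy = TRUE, angle_change = FALSE)
  if (magnitude_zero_crossings) {
    plan <- c(plan, list(speed = FALSE, accel = FALSE, curvature = FALSE))
  }
  plan
}

feature_names_for <- function(magnitude_zero_crossings = FALSE) {
  series <- c("vx", "vy", "speed", "accel", "angle_change", "curvature")
  stats <- c("mean", "sd", "min", "max", "q1", "median", "q3")
  base <- as.vector(t(outer(series, stats, paste, sep = "_")))
  zc <- paste0(names(zc_plan(magnitude_zero_crossings)), "_zero_crossings")
  c(base, zc, "path_length", "net_displacement", "straightness")
}

# Core feature computation on precomputed series for the window starting at
# position `s` (1-based) of length `nw` within the parent vectors.
features_from_series <- function(ser, s, nw, x, y, real, tol = 0,
                                 magnitude_zero_crossings = FALSE) {
  iv <- s:(s + nw - 2L)          # velocity-type indices
  ia <- s:(s + nw - 3L)          # angle/accel/curvature indices
  series_vals <- list(
    vx = ser$vx[iv], vy = ser$vy[iv], speed = ser$speed[iv],
    accel = ser$accel[ia], angle_change = ser$angle_change[ia],
    curvature = ser$curvature[ia]
  )
  series_mask <- list(
    vx = ser$valid_v[iv], vy = ser$valid_v[iv], speed = ser$valid_v[iv],
    accel = ser$valid_a[ia], angle_change = ser$valid_a[ia],
    curvature = ser$valid_curv[ia]
  )
  out <- numeric(0)
  for (nm in names(series_vals)) {
    sm <- summarize_series(series_vals[[nm]], series_mask[[nm]])
    names(sm) <- paste(nm, names(sm), sep = "_")
    out <- c(out, sm)
  }
  plan <- zc_plan(magnitude_zero_crossings)
  for (nm in names(plan)) {
    out[paste0(nm, "_zero_crossings")] <- zero_crossings(
      series_vals[[nm]], signed = plan[[nm]], mask = series_mask[[nm]], tol = tol)
  }
  ipos <- s:(s + nw - 1L)
  rp <- which(real[ipos])
  valid_steps <- series_mask$vx
  path <- sum(ser$step_len[iv][valid_steps])
  net <- if (length(rp) >= 2) {
    sqrt((x[ipos][rp[length(rp)]] - x[ipos][rp[1]])^2 +
         (y[ipos][rp[length(rp)]] - y[ipos][rp[1]])^2)
  } else {
    NA_real_
  }
  straight <- if (is.na(net) || path == 0) 0 else min(1, net / path)
  out["path_length"] <- path
  out["net_displacement"] <- net
  out["straightness"] <- straight
  out
}

#' Extract the flight feature vector of one segment
#'
#' Applies [summarize_series()] to every kinematic series of the segment,
#' counts zero-crossings (signed for `vx`/`vy`, exact zeros for the
#' non-negative `angle_change`), and adds the geometric scalars
#' `path_length` (mm, over valid steps), `net_displacement` (mm, first to
#' last real position) and `straightness` (net/path, clamped to `[0, 1]`;
#' 0 when the path length is 0).
#'
#' @param segment Data frame of segment samples (`x_mm`, `y_mm`, `real_flag`).
#' @param fps Frames per second.
#' @param magnitude_zero_crossings Also emit exact-zero counts for speed,
#'   acceleration and curvature (default `FALSE`).
#' @param zero_tol Zero tolerance for crossings (default 0).
#' @return A named numeric feature vector.
#' @export
extract_segment_features <- function(segment, fps = 50,
                                     magnitude_zero_crossings = FALSE,
                                     zero_tol = 0) {
  if (nrow(segment) < 3) stop("segment must have at least 3 samples", call. = FALSE)
  ser <- compute_series(segment$x_mm, segment$y_mm, segment$real_flag, fps)
  features_from_series(ser, 1L, nrow(segment),
                       segment$x_mm, segment$y_mm, segment$real_flag,
                       tol = zero_tol,
                       magnitude_zero_crossings = magnitude_zero_crossings)
}

#' Build the segment-by-feature table
#'
#' Computes the full feature vector for every segment descriptor, attaching
#' provenance columns (`trial_id`, `track_id`, `segment_index`, `start_s`,
#' `quality` and any label columns present on `segments`). Segments whose
#' modelling features cannot be computed (e.g. all samples interpolated) are
#' dropped with a warning.
#'
#' @param tracks Interpolated track tibble (frame step 1 per track).
#' @param segments Segment descriptor tibble from [window_tracks()].
#' @param fps Frames per second.
#' @inheritParams extract_segment_features
#' @return A tibble with one row per usable segment.
#' @export
build_feature_table <- function(tracks, segments, fps = 50,
                                magnitude_zero_crossings = FALSE,
                                zero_tol = 0) {
  assert_track_table(tracks)
  if (nrow(segments) == 0) stop("no segments to featurise", call. = FALSE)
  fnames <- feature_names_for(magnitude_zero_crossings)
  key_tracks <- paste(tracks$trial_id, tracks$track_id, sep = "\r")
  key_segs <- paste(segments$trial_id, segments$track_id, sep = "\r")
  track_groups <- split(seq_len(nrow(tracks)), key_tracks)

  mat <- matrix(NA_real_, nrow = nrow(segments), ncol = length(fnames),
                dimnames = list(NULL, fnames))
  for (key in unique(key_segs)) {
    rows <- track_groups[[key]]
    if (is.null(rows)) {
      stop("segment refers to a track absent from `tracks`", call. = FALSE)
    }
    x <- tracks$x_mm[rows]; y <- tracks$y_mm[rows]
    real <- tracks$real_flag[rows]
    frames <- tracks$frame[rows]
    ser <- compute_series(x, y, real, fps)
    seg_rows <- which(key_segs == key)
    for (si in seg_rows) {
      s <- segments$start_frame[si] - frames[1] + 1L
      mat[si, ] <- features_from_series(
        ser, s, segments$n_w[si], x, y, real,
        tol = zero_tol, magnitude_zero_crossings = magnitude_zero_crossings)
    }
  }

  prov_cols <- intersect(
    c("trial_id", "track_id", "segment_index", "start_s", "quality",
      "net_type", "strain", "resistance"),
    names(segments)
  )
  out <- dplyr::bind_cols(segments[, prov_cols], tibble::as_tibble(mat))
  usable <- stats::complete.cases(mat)
  if (!all(usable)) {
    warning(sprintf("dropped %d segment(s) with incomputable features",
                    sum(!usable)), call. = FALSE)
    out <- out[usable, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no usable segments after feature extraction", call. = FALSE)
  out
}

#' Names of the modelling feature columns of a feature table
#'
#' @param feature_table A tibble from [build_feature_table()].
#' @return Character vector of feature column names (provenance excluded).
#' @export
feature_columns <- function(feature_table) {
  setdiff(names(feature_table),
          c("trial_id", "track_id", "segment_index", "start_s", "quality",
            "net_type", "strain", "resistance"))
}
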