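#' Drop tracks shorter than a minimum duration
#'
#' Keeps tracks whose observed duration (last minus first timestamp) is at
#' least `min_s` seconds; the boundary is inclusive.
#'
#' @param tracks A track tibble (possibly many tracks).
#' @param min_s Minimum duration in seconds (default 1).
#' @return The filtered track tibble.
#' @export
filter_min_duration <- function(tracks, min_s = 1) {
  assert_track_table(tracks)
  if (nrow(tracks) == 0) return(tracks)
  tracks |>
    dplyr::group_by(.data$trial_id, .data$track_id) |>
    dplyr::filter(max(.data$t_s) - min(.data$t_s) >= min_s) |>
    dplyr::ungroup()
}

interpolate_one <- function(track) {
  n <- nrow(track)
  if (n < 2L) stop("cannot interpolate a track with fewer than 2 samples", call. = FALSE)
  frames <- track$frame
  if (any(diff(frames) <= 0)) {
    stop("track frames must be strictly increasing", call. = FALSE)
  }
  full <- seq.int(frames[1], frames[n])
  if (length(full) == n) return(track)
  dt <- (track$t_s[n] - track$t_s[1]) / (frames[n] - frames[1])
  x <- stats::approx(frames, track$x_mm, xout = full)$y
  y <- stats::approx(frames, track$y_mm, xout = full)$y
  observed <- full %in% frames
  real <- logical(length(full))
  real[observed] <- track$real_flag
  tibble::tibble(
    trial_id = track$trial_id[1],
    track_id = track$track_id[1],
    frame = as.integer(full),
    t_s = track$t_s[1] + (full - frames[1]) * dt,
    x_mm = x,
    y_mm = y,
    real_flag = real
  )
}

#' Fill missing frames by linear interpolation
#'
#' Every missing interior frame index of each track is filled by linear
#' interpolation of `x_mm` and `y_mm` against frame index (a uniform clock);
#' inserted samples carry `real_flag = FALSE`. Endpoints are untouched and the
#' output frame sequence of each track has step 1.
#'
#' @param tracks A track tibble with strictly increasing frames per track.
#' @return The gap-free track tibble.
#' @export
interpolate_gaps <- function(tracks) {
  assert_track_table(tracks)
  if (nrow(tracks) == 0) return(tracks)
  tracks |>
    dplyr::group_by(.data$trial_id, .data$track_id) |>
    dplyr::group_split() |>
    purrr::map(interpolate_one) |>
    dplyr::bind_rows()
}

#' Score the information quality of a segment
#'
#' The score is `sum(r_i^2) / L` over the maximal runs of consecutive
#' interpolated samples (lengths `r_i`) in a segment of length `L`. It is 0
#' iff the segment is gap-free, and grows quadratically with the length of a
#' consecutive gap, so long interpolated stretches are penalised more than the
#' same number of scattered interpolated samples. Larger scores denote lower
#' information quality.
#'
#' @param segment Either a logical vector of `real_flag`s or a data frame with
#'   a `real_flag` column.
#' @return A non-negative quality score.
#' @export
segment_quality <- function(segment) {
  real <- if (is.data.frame(segment)) segment$real_flag else segment
  if (!is.logical(real)) stop("`segment` must carry logical real/interpolated flags",
                              call. = FALSE)
  L <- length(real)
  if (L == 0) return(0)
  runs <- rle(!real)
  sum(runs$lengths[runs$values]^2) / L
}

#' Split one gap-free track into fixed-duration overlapping windows
#'
#' Emits full windows only, starting at frame offsets `0, stride, 2*stride,
#' ...` where `n_w = round(window_s * fps)` and
#' `stride = round((window_s - overlap_s) * fps)`. A track of `n` frames
#' yields `floor((n - n_w) / stride) + 1` windows when `n >= n_w`, else none.
#'
#' @param track A single interpolated track (frame step 1).
#' @param window_s Window length, seconds.
#' @param overlap_s Window overlap, seconds (`0 <= overlap_s < window_s`).
#' @param fps Frames per second.
#' @return A tibble of segment descriptors: `trial_id`, `track_id`,
#'   `segment_index`, `start_frame`, `start_s`, `n_w`, `quality`.
#' @export
window_track <- function(track, window_s = 7.5, overlap_s = 7, fps = 50) {
  n_w <- as.integer(round(window_s * fps))
  stride <- as.integer(round((window_s - overlap_s) * fps))
  if (stride <= 0L) stop("window stride must be positive (overlap too large)", call. = FALSE)
  if (n_w < 2L) stop("window must span at least 2 frames", call. = FALSE)
  n <- nrow(track)
  if (n < n_w) {
    return(tibble::tibble(
      trial_id = character(), track_id = character(), segment_index = integer(),
      start_frame = integer(), start_s = numeric(), n_w = integer(),
      quality = numeric()
    ))
  }
  if (any(diff(track$frame) != 1L)) {
    stop("`track` must be interpolated to frame step 1 before windowing", call. = FALSE)
  }
  k <- (n - n_w) %/% stride
  starts <- 1L + (0:k) * stride
  quality <- vapply(starts, function(s) {
    segment_quality(track$real_flag[s:(s + n_w - 1L)])
  }, numeric(1))
  tibble::tibble(
    trial_id = track$trial_id[1],
    track_id = track$track_id[1],
    segment_index = seq_along(starts),
    start_frame = track$frame[starts],
    start_s = track$t_s[starts],
    n_w = n_w,
    quality = quality
  )
}

#' Window every track of a study
#'
#' Applies [window_track()] per track and attaches trial labels when metadata
#' is given.
#'
#' @param tracks An interpolated track tibble.
#' @param trials Optional trial metadata (`trial_id`, `net_type`, `strain`,
#'   `resistance`) joined onto the segments.
#' @inheritParams window_track
#' @return A segment descriptor tibble.
#' @export
window_tracks <- function(tracks, trials = NULL, window_s = 7.5, overlap_s = 7,
                          fps = 50) {
  assert_track_table(tracks)
  segs <- tracks |>
    dplyr::group_by(.data$trial_id, .data$track_id) |>
    dplyr::group_split() |>
    purrr::map(window_track, window_s = window_s, overlap_s = overlap_s, fps = fps) |>
    dplyr::bind_rows()
  if (!is.null(trials) && nrow(segs) > 0) {
    segs <- dplyr::left_join(segs, tibble::as_tibble(trials),
                             by = "trial_id")
  }
  segs
}

# Extract the sample window of one segment descriptor row from the
# interpolated track table. Internal; feature extraction slices vectors
# directly for speed.
segment_samples <- function(tracks, segment_row) {
  rows <- tracks$trial_id == segment_row$trial_id &
    tracks$track_id == segment_row$track_id &
    tracks$frame >= segment_row$start_frame &
    tracks$frame < segment_row$start_frame + segment_row$n_w
  tracks[rows, , drop = FALSE]
}

# Mutual information between a discretised feature and a binary label.
# Equal-frequency binning with `bins` bins (duplicate quantiles merged) and
# Miller-Madow bias correction, so estimates from subsets of different sizes
# are comparable: the plug-in estimator inflates on small samples, which
# would otherwise make near-empty quality strata look informative.
mutual_information_binned <- function(x, label, bins = 10) {
  ok <- is.finite(x)
  x <- x[ok]
  label <- label[ok]
  n <- length(x)
  if (n < 2 || length(unique(label)) < 2) return(c(mi = NA_real_, se = NA_real_))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(c(mi = 0, se = 0))
  bx <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(bx, label)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  logratio <- log(p / outer(px, py))
  terms <- p * logratio
  plugin <- sum(terms[p > 0])
  bias <- (sum(tab > 0) - sum(rowSums(tab) > 0) - sum(colSums(tab) > 0) + 1) /
    (2 * n)
  # delta-method standard error of the plug-in estimate
  second <- sum((p * logratio^2)[p > 0])
  se <- sqrt(max(0, second - plugin^2) / n)
  c(mi = max(0, plugin - bias), se = se)
}

#' Select the segment-quality threshold by mutual information
#'
#' For each feature and each candidate threshold `q`, computes the mutual
#' information between the (equal-frequency discretised) feature and the class
#' label among segments with quality `<= q` (Miller-Madow corrected). Each
#' feature votes for the threshold that maximises its information content;
#' thresholds whose MI lies within one standard error of that maximum count
#' as ties, resolved toward the largest threshold so that statistically
#' indistinguishable information keeps more data. The final threshold is the
#' mean of the per-feature optima weighted by each feature's maximal mutual
#' information.
#'
#' @param feature_table Data frame of numeric feature columns, one row per
#'   segment (provenance columns are ignored).
#' @param quality Numeric vector of segment quality scores.
#' @param labels Class labels, one per segment.
#' @param grid Candidate thresholds; default `NULL` uses 0 plus the deciles of
#'   the observed nonzero qualities.
#' @param bins Number of equal-frequency bins for the estimator (default 10).
#' @return A list with elements `threshold`, and `per_feature` (a tibble with
#'   the per-feature best threshold and weight).
#' @export
select_quality_threshold <- function(feature_table, quality, labels,
                                     grid = NULL, bins = 10) {
  feats <- feature_table[vapply(feature_table, is.numeric, logical(1))]
  feats <- feats[setdiff(names(feats), c("start_s", "segment_index", "quality",
                                         "start_frame", "n_w"))]
  if (ncol(feats) == 0) stop("no numeric feature columns found", call. = FALSE)
  if (length(quality) != nrow(feats) || length(labels) != nrow(feats)) {
    stop("`quality` and `labels` must have one entry per feature row", call. = FALSE)
  }
  if (is.null(grid)) {
    nz <- quality[quality > 0]
    grid <- if (length(nz) == 0) 0 else
      unique(c(0, stats::quantile(nz, probs = seq(0.1, 1, by = 0.1),
                                  type = 7, names = FALSE)))
  }
  grid <- sort(unique(grid))
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)

  # a candidate must retain enough segments for a stable estimate and both
  # classes; near-empty strata are skipped rather than scored
  min_keep <- max(20, 2 * bins)
  usable <- vapply(grid, function(q) {
    keep <- quality <= q
    sum(keep) >= min_keep && length(unique(labels[keep])) >= 2
  }, logical(1))
  if (!any(usable)) {
    stop("no candidate threshold retains at least two classes", call. = FALSE)
  }
  grid <- grid[usable]

  mi <- se <- matrix(NA_real_, nrow = length(grid), ncol = ncol(feats),
                     dimnames = list(NULL, names(feats)))
  for (gi in seq_along(grid)) {
    keep <- quality <= grid[gi]
    lab <- labels[keep]
    for (fi in seq_len(ncol(feats))) {
      est <- mutual_information_binned(feats[[fi]][keep], lab, bins = bins)
      if (!anyNA(est)) {
        mi[gi, fi] <- est[["mi"]]
        se[gi, fi] <- est[["se"]]
      }
    }
  }

  per_feature <- purrr::map(seq_len(ncol(feats)), function(fi) {
    v <- mi[, fi]
    if (all(is.na(v))) return(NULL)
    best_i <- which.max(v)
    # statistical ties (within one SE of the max) resolve to the largest
    # threshold, keeping more data
    tied <- !is.na(v) & v >= v[best_i] - se[best_i, fi]
    q_star <- max(grid[tied])
    tibble::tibble(feature = names(feats)[fi], best_threshold = q_star,
                   weight = v[best_i])
  }) |> dplyr::bind_rows()

  w <- pmax(per_feature$weight, 0)
  threshold <- if (sum(w) > 0) {
    sum(w * per_feature$best_threshold) / sum(w)
  } else {
    max(grid)
  }
  list(threshold = threshold, per_feature = per_feature)
}

#' Filter segments by quality threshold
#'
#' Keeps segments with quality less than or equal to `threshold` (inclusive
#' boundary). Idempotent.
#'
#' @param segments Segment descriptor tibble with a `quality` column.
#' @param threshold Non-negative quality threshold.
#' @return The filtered segment tibble.
#' @export
apply_quality_filter <- function(segments, threshold) {
  stopifnot_scalar(threshold, "threshold", lower = 0)
  kept <- segments[segments$quality <= threshold, , drop = FALSE]
  pkg_log("quality filter: kept %d of %d segments (threshold %.4g)",
          nrow(kept), nrow(segments), threshold)
  kept
}
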