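#' Behavioural parameters for the flight simulator
#'
#' Bundles the knobs of the discrete-time correlated-random-walk flight model.
#' Headings evolve by wrapped Gaussian noise whose standard deviation is
#' `1 / sqrt(turn_concentration)` (higher concentration = straighter flight),
#' are flipped by `pi` at Poisson-rate reversal events, and may additionally
#' receive uncorrelated sharp turns ("bursts"). Per-frame displacement is
#' `speed / fps` along the current heading, with speed drawn from a folded
#' normal around `mean_speed`, and exactly zero on pause frames. Pauses arrive
#' in bouts with geometric run lengths so that resting/hovering produces runs
#' of zero-displacement frames, as tracking data does.
#'
#' @param mean_speed Mean flight speed, mm/s (> 0).
#' @param speed_sd Per-frame speed standard deviation, mm/s (>= 0).
#' @param turn_concentration Heading persistence, dimensionless >= 0. `Inf`
#'   means perfectly straight flight; 0 means uniformly random headings.
#' @param reversal_rate Expected heading reversals (flips by `pi`) per second.
#' @param pause_prob Marginal probability that any given frame is a
#'   zero-displacement frame, in `[0, 1]`.
#' @param turn_burst_prob Per-frame probability of an additional sharp turn
#'   drawn uniformly from `(-pi, pi]`. Default 0.
#' @param pause_run_mean Mean length (frames) of a pause bout; pauses cluster
#'   into geometric runs with this mean while keeping the marginal frequency at
#'   `pause_prob`. Default 4.
#' @param individual_sd Standard deviation (log scale) of per-track log-normal
#'   multipliers applied to `mean_speed`, `turn_concentration`,
#'   `reversal_rate` and `turn_burst_prob`, modelling individual behavioural
#'   variation between mosquitoes. Default 0 (homogeneous).
#' @param horizontal_bias Per-frame attraction of the heading toward the
#'   horizontal axis (drift `-horizontal_bias * sin(2 * heading)`), modelling
#'   the horizontal sweeping flight seen along a bednet surface. Default 0
#'   (isotropic).
#'
#' @return An object of class `behaviour_params` (a named list).
#' @seealso [ut_flight_params()], [ol_flight_params()], [simulate_track()]
#' @export
behaviour_params <- function(mean_speed,
                             speed_sd,
                             turn_concentration,
                             reversal_rate,
                             pause_prob,
                             turn_burst_prob = 0,
                             pause_run_mean = 4,
                             individual_sd = 0,
                             horizontal_bias = 0) {
  if (!is.numeric(mean_speed) || length(mean_speed) != 1L ||
      !is.finite(mean_speed) || mean_speed < 0) {
    stop("`mean_speed` must be a single finite non-negative number", call. = FALSE)
  }
  stopifnot_scalar(speed_sd, "speed_sd", lower = 0)
  if (!is.numeric(turn_concentration) || length(turn_concentration) != 1L ||
      is.na(turn_concentration) || turn_concentration < 0) {
    stop("`turn_concentration` must be a single non-negative number (Inf allowed)",
         call. = FALSE)
  }
  stopifnot_scalar(reversal_rate, "reversal_rate", lower = 0)
  stopifnot_scalar(pause_prob, "pause_prob", lower = 0, upper = 1)
  stopifnot_scalar(turn_burst_prob, "turn_burst_prob", lower = 0, upper = 1)
  stopifnot_scalar(pause_run_mean, "pause_run_mean", lower = 1)
  stopifnot_scalar(individual_sd, "individual_sd", lower = 0)
  stopifnot_scalar(horizontal_bias, "horizontal_bias", lower = 0)
  structure(
    list(
      mean_speed = mean_speed, speed_sd = speed_sd,
      turn_concentration = turn_concentration, reversal_rate = reversal_rate,
      pause_prob = pause_prob, turn_burst_prob = turn_burst_prob,
      pause_run_mean = pause_run_mean, individual_sd = individual_sd,
      horizontal_bias = horizontal_bias
    ),
    class = "behaviour_params"
  )
}

#' Preset behaviour at an untreated net
#'
#' Relatively directed flight with occasional sharp turns and frequent short
#' resting/hovering bouts; speeds on the scale reported for untreated-net
#' trajectories (hundreds of mm/s).
#'
#' @return A [behaviour_params()] object.
#' @export
ut_flight_params <- function() {
  behaviour_params(
    mean_speed = 420, speed_sd = 100,
    turn_concentration = 3, reversal_rate = 0.5,
    pause_prob = 0.10, turn_burst_prob = 0.25,
    pause_run_mean = 3, individual_sd = 0.6,
    horizontal_bias = 0.5
  )
}

#' Preset behaviour at an Olyset (permethrin) net
#'
#' Erratic, convoluted flight: low heading persistence, frequent sharp turns
#' and direction reversals, faster flight and almost no resting pauses --
#' the insecticide-disrupted regime.
#'
#' @return A [behaviour_params()] object.
#' @export
ol_flight_params <- function() {
  behaviour_params(
    mean_speed = 560, speed_sd = 140,
    turn_concentration = 0.6, reversal_rate = 6,
    pause_prob = 0.015, turn_burst_prob = 0.2,
    pause_run_mean = 3, individual_sd = 0.6,
    horizontal_bias = 0.05
  )
}

#' Specification of one simulated trial
#'
#' A trial emulates a 2-h experiment releasing `n_mosquitoes` mosquitoes around
#' one net. Track durations follow a log-normal law truncated to
#' `[1, remaining time]` seconds, giving means of order 10--25 s with a heavy
#' right tail. Insecticide-susceptible mosquitoes at an Olyset net are censored
#' after `mortality_cutoff_s` (default 1800 s = 30 min): no track starts after
#' the cutoff and tracks crossing it are truncated.
#'
#' @param trial_id Trial identifier (character scalar).
#' @param net_type `"UT"` (untreated) or `"OL"` (Olyset).
#' @param strain Strain identifier.
#' @param resistance `"IS"` (susceptible) or `"IR"` (resistant).
#' @param n_mosquitoes Number of released mosquitoes (default 25).
#' @param duration_s Trial duration, seconds (default 7200).
#' @param fps Frame rate, frames/s (default 50).
#' @param arena Field-of-view width and height, mm (default `c(1200, 1000)`).
#' @param mortality_cutoff_s Censoring time in seconds; `NULL` (the default)
#'   applies 1800 s for IS mosquitoes at an OL net and none otherwise; `NA`
#'   disables censoring.
#' @param track_meanlog,track_sdlog Log-normal track-duration parameters
#'   (seconds; defaults `log(12)` and 0.9).
#' @param gap_prob Per-frame dropout probability for tracking gaps (default 0.02).
#' @param gap_max_run Maximum dropout run length, frames (default 12).
#' @param n_tracks_per_mosquito Mean extra tracks per mosquito beyond the first
#'   (Poisson); default 0, i.e. one track per released mosquito.
#' @param seed Integer seed for the trial.
#'
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(trial_id, net_type, strain, resistance,
                       n_mosquitoes = 25, duration_s = 7200, fps = 50,
                       arena = c(1200, 1000), mortality_cutoff_s = NULL,
                       track_meanlog = log(12), track_sdlog = 0.9,
                       gap_prob = 0.02, gap_max_run = 12,
                       n_tracks_per_mosquito = 0, seed = 1L) {
  net_type <- match.arg(net_type, c("UT", "OL"))
  resistance <- match.arg(resistance, c("IS", "IR"))
  stopifnot_scalar(duration_s, "duration_s", lower = 1e-9)
  stopifnot_scalar(fps, "fps", lower = 1e-9)
  stopifnot_scalar(n_mosquitoes, "n_mosquitoes", lower = 1)
  if (length(arena) != 2L || any(!is.finite(arena)) || any(arena <= 0)) {
    stop("`arena` must be two positive numbers (width, height) in mm", call. = FALSE)
  }
  if (is.null(mortality_cutoff_s)) {
    mortality_cutoff_s <- if (net_type == "OL" && resistance == "IS") {
      min(1800, duration_s)
    } else {
      NA_real_
    }
  }
  if (!is.na(mortality_cutoff_s)) {
    stopifnot_scalar(mortality_cutoff_s, "mortality_cutoff_s", lower = 0)
    if (mortality_cutoff_s > duration_s) {
      stop("`mortality_cutoff_s` cannot exceed `duration_s`", call. = FALSE)
    }
  }
  stopifnot_scalar(gap_prob, "gap_prob", lower = 0, upper = 1)
  stopifnot_scalar(gap_max_run, "gap_max_run", lower = 1)
  structure(
    list(
      trial_id = as.character(trial_id), net_type = net_type,
      strain = as.character(strain), resistance = resistance,
      n_mosquitoes = as.integer(n_mosquitoes), duration_s = duration_s,
      fps = fps, arena = as.numeric(arena),
      mortality_cutoff_s = mortality_cutoff_s,
      track_meanlog = track_meanlog, track_sdlog = track_sdlog,
      gap_prob = gap_prob, gap_max_run = gap_max_run,
      n_tracks_per_mosquito = n_tracks_per_mosquito,
      seed = as.integer(seed)
    ),
    class = "trial_spec"
  )
}

#' Simulate a single flight track
#'
#' Runs the correlated random walk of [behaviour_params()] for `duration_s`
#' seconds at `fps` frames per second inside a reflecting rectangular arena.
#' Positions start uniformly at random in the arena; boundary crossings are
#' folded back (specular reflection). All samples are flagged real.
#'
#' @param params A [behaviour_params()] object.
#' @param duration_s Track duration in seconds (>= `2/fps`).
#' @param fps Frames per second.
#' @param arena `c(width_mm, height_mm)`.
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param trial_id,track_id Provenance identifiers attached to the output.
#' @param start_s Time of the first frame within the trial, seconds.
#'
#' @return A track tibble with columns `trial_id`, `track_id`, `frame`, `t_s`,
#'   `x_mm`, `y_mm`, `real_flag`.
#' @export
simulate_track <- function(params, duration_s, fps = 50, arena = c(1200, 1000),
                           seed = 1L, trial_id = "T1", track_id = 1L,
                           start_s = 0) {
  if (!inherits(params, "behaviour_params")) {
    stop("`params` must be a `behaviour_params` object", call. = FALSE)
  }
  stopifnot_scalar(duration_s, "duration_s", lower = 2 / fps)
  n <- max(2L, as.integer(round(duration_s * fps)))

  local_seed(seed, {
    mult <- function() {
      if (params$individual_sd > 0) stats::rlnorm(1, 0, params$individual_sd) else 1
    }
    m_speed <- mult(); m_kappa <- mult(); m_rev <- mult(); m_burst <- mult()
    m_pause <- mult()

    kappa <- params$turn_concentration * m_kappa
    sigma <- if (is.infinite(kappa)) 0 else if (kappa <= 0) 50 else min(50, 1 / sqrt(kappa))

    n_steps <- n - 1L
    # Pause bout structure: alternating geometric runs preserving the marginal
    # per-frame pause probability.
    pause <- rep(FALSE, n_steps)
    p <- min(0.5, params$pause_prob * m_pause)
    if (params$pause_prob >= 1) p <- 1
    if (p > 0 && p < 1) {
      L <- params$pause_run_mean
      M <- L * (1 - p) / p  # mean active-run length
      pos <- 0L
      state <- stats::runif(1) < p
      while (pos < n_steps) {
        len <- if (state) 1L + stats::rgeom(1, min(1, 1 / L)) else
          1L + stats::rgeom(1, min(1, 1 / M))
        idx <- seq.int(pos + 1L, min(n_steps, pos + len))
        pause[idx] <- state
        pos <- pos + len
        state <- !state
      }
    } else if (p >= 1) {
      pause[] <- TRUE
    }

    speed <- abs(stats::rnorm(n_steps, params$mean_speed * m_speed, params$speed_sd))
    turn_noise <- if (sigma > 0) {
      wrap_angle(stats::rnorm(n_steps, 0, sigma))
    } else {
      numeric(n_steps)
    }
    p_rev <- 1 - exp(-params$reversal_rate * m_rev / fps)
    reversals <- stats::runif(n_steps) < p_rev
    p_burst <- min(1, params$turn_burst_prob * m_burst)
    bursts <- stats::runif(n_steps) < p_burst
    burst_angle <- ifelse(bursts, stats::runif(n_steps, -pi, pi), 0)

    increments <- turn_noise + pi * reversals + burst_angle
    theta0 <- stats::runif(1, -pi, pi)
    if (params$horizontal_bias > 0) {
      # heading attracted toward 0 or pi (horizontal sweeping along the net)
      heading <- numeric(n_steps)
      heading[1] <- theta0
      b <- params$horizontal_bias
      for (k in seq_len(n_steps - 1L)) {
        heading[k + 1L] <- heading[k] - b * sin(2 * heading[k]) + increments[k]
      }
    } else {
      # heading of step k is theta0 plus the turning accumulated before step k
      heading <- theta0 + cumsum(c(0, increments[-n_steps]))
    }

    step_len <- ifelse(pause, 0, speed / fps)
    dx <- step_len * cos(heading)
    dy <- step_len * sin(heading)

    x0 <- stats::runif(1, 0, arena[1])
    y0 <- stats::runif(1, 0, arena[2])
    x <- fold_reflect(c(x0, x0 + cumsum(dx)), arena[1])
    y <- fold_reflect(c(y0, y0 + cumsum(dy)), arena[2])

    frame0 <- as.integer(round(start_s * fps))
    frames <- frame0 + seq_len(n) - 1L
    tibble::tibble(
      trial_id = as.character(trial_id),
      track_id = as.character(track_id),
      frame = frames,
      t_s = frames / fps,
      x_mm = x,
      y_mm = y,
      real_flag = TRUE
    )
  })
}

#' Remove interior samples to emulate tracking dropouts
#'
#' Marks interior frames for removal independently with probability `gap_prob`,
#' then breaks removal runs longer than `gap_max_run` by reinstating every
#' `(gap_max_run + 1)`-th frame. The first and last samples are never removed,
#' so the observed duration is unchanged.
#'
#' @param track A track tibble (single track, >= 2 rows).
#' @param gap_prob Per-frame dropout probability in `[0, 1]`.
#' @param gap_max_run Maximum run of consecutive removed frames (>= 1).
#' @param seed Integer seed.
#'
#' @return The track tibble with some interior rows removed; frames remain
#'   strictly increasing.
#' @export
inject_gaps <- function(track, gap_prob, gap_max_run = 12, seed = 1L) {
  assert_track_table(track, "track")
  n <- nrow(track)
  if (n < 2L) stop("`track` must have at least 2 samples", call. = FALSE)
  stopifnot_scalar(gap_prob, "gap_prob", lower = 0, upper = 1)
  if (gap_prob == 0 || n == 2L) return(track)

  local_seed(seed, {
    remove <- c(FALSE, stats::runif(n - 2L) < gap_prob, FALSE)
    runs <- rle(remove)
    if (any(runs$values & runs$lengths > gap_max_run)) {
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (i in which(runs$values & runs$lengths > gap_max_run)) {
        idx <- seq.int(starts[i], ends[i])
        keep_at <- idx[seq_along(idx) %% (gap_max_run + 1L) == 0L]
        remove[keep_at] <- FALSE
      }
    }
    if (all(remove[-c(1L, n)])) {
      stop("gap law would remove all interior points", call. = FALSE)
    }
    track[!remove, , drop = FALSE]
  })
}

#' Simulate one trial of released mosquitoes
#'
#' For each released mosquito, samples one or more track start times and
#' heavy-tailed durations, simulates each track with the behaviour parameters
#' of the trial's net type, applies mortality censoring (no starts after the
#' cutoff; crossing tracks truncated) and injects tracking gaps.
#'
#' @param spec A [trial_spec()] object.
#' @param ut_params,ol_params [behaviour_params()] for the untreated and
#'   Olyset regimes; the one matching `spec$net_type` is used.
#'
#' @return A track tibble covering all tracks of the trial; `track_id` values
#'   are unique within the trial.
#' @export
simulate_trial <- function(spec, ut_params = ut_flight_params(),
                           ol_params = ol_flight_params()) {
  if (!inherits(spec, "trial_spec")) {
    stop("`spec` must be a `trial_spec` object", call. = FALSE)
  }
  params <- if (spec$net_type == "OL") ol_params else ut_params
  cutoff <- spec$mortality_cutoff_s
  max_start <- if (is.na(cutoff)) spec$duration_s - 1 else min(spec$duration_s - 1, cutoff)
  max_start <- max(0, max_start)

  draws <- local_seed(spec$seed, {
    per_mosquito <- 1L + if (spec$n_tracks_per_mosquito > 0) {
      stats::rpois(spec$n_mosquitoes, spec$n_tracks_per_mosquito)
    } else {
      integer(spec$n_mosquitoes)
    }
    total <- sum(per_mosquito)
    start <- stats::runif(total, 0, max_start)
    dur <- exp(stats::rnorm(total, spec$track_meanlog, spec$track_sdlog))
    list(per_mosquito = per_mosquito, start = start, dur = dur)
  })

  total <- sum(draws$per_mosquito)
  out <- vector("list", total)
  for (k in seq_len(total)) {
    start <- draws$start[k]
    dur <- min(max(1, draws$dur[k]), spec$duration_s - start)
    if (!is.na(cutoff) && start + dur > cutoff) {
      dur <- cutoff - start
    }
    dur <- max(dur, 2 / spec$fps)
    tr <- simulate_track(
      params, dur, fps = spec$fps, arena = spec$arena,
      seed = derive_seed(spec$seed, k),
      trial_id = spec$trial_id, track_id = sprintf("tr%04d", k),
      start_s = start
    )
    if (spec$gap_prob > 0) {
      tr <- inject_gaps(tr, spec$gap_prob, spec$gap_max_run,
                        seed = derive_seed(spec$seed, 100000L + k))
    }
    out[[k]] <- tr
  }
  dplyr::bind_rows(out)
}

default_strain_plan <- function() {
  tibble::tibble(
    strain = c("Kisumu", "NGousso", "VK7", "Banfora"),
    resistance = c("IS", "IS", "IR", "IR")
  )
}

#' Simulate a full study of UT and OL trials
#'
#' Emits `n_ut_trials + n_ol_trials` trials, cycling the strain plan within
#' each arm so that every strain appears in both arms, with per-trial seeds
#' derived from the master seed.
#'
#' @param n_ut_trials,n_ol_trials Number of untreated and Olyset trials.
#' @param strain_plan Data frame with columns `strain` and `resistance`;
#'   default: Kisumu/IS, NGousso/IS, VK7/IR, Banfora/IR.
#' @param ut_params,ol_params Behaviour presets for the two regimes.
#' @param seed Master integer seed.
#' @param check_balance If `TRUE` (default), error when an arm has fewer trials
#'   than strains, which would leave a strain-by-net cell empty.
#' @param ... Further arguments passed to [trial_spec()] (e.g. `n_mosquitoes`,
#'   `duration_s`, `gap_prob`).
#'
#' @return An object of class `flight_study`: a list with elements `tracks`
#'   (one track table for the whole study) and `trials` (metadata tibble with
#'   `trial_id`, `net_type`, `strain`, `resistance`).
#' @export
simulate_study <- function(n_ut_trials, n_ol_trials,
                           strain_plan = default_strain_plan(),
                           ut_params = ut_flight_params(),
                           ol_params = ol_flight_params(),
                           seed = 1L, check_balance = TRUE, ...) {
  stopifnot_scalar(n_ut_trials, "n_ut_trials", lower = 0)
  stopifnot_scalar(n_ol_trials, "n_ol_trials", lower = 0)
  strain_plan <- tibble::as_tibble(strain_plan)
  if (!all(c("strain", "resistance") %in% names(strain_plan)) ||
      nrow(strain_plan) == 0) {
    stop("`strain_plan` must have columns `strain` and `resistance`", call. = FALSE)
  }
  if (check_balance && (n_ut_trials < nrow(strain_plan) ||
                        n_ol_trials < nrow(strain_plan))) {
    stop("each arm needs at least one trial per strain; ",
         "reduce `strain_plan` or increase trial counts", call. = FALSE)
  }

  meta <- dplyr::bind_rows(
    tibble::tibble(net_type = rep("UT", n_ut_trials)),
    tibble::tibble(net_type = rep("OL", n_ol_trials))
  )
  ns <- nrow(strain_plan)
  idx <- c(
    if (n_ut_trials > 0) (seq_len(n_ut_trials) - 1L) %% ns + 1L else integer(),
    if (n_ol_trials > 0) (seq_len(n_ol_trials) - 1L) %% ns + 1L else integer()
  )
  meta$strain <- strain_plan$strain[idx]
  meta$resistance <- strain_plan$resistance[idx]
  meta$trial_id <- sprintf("%s%02d", meta$net_type, stats::ave(
    seq_len(nrow(meta)), meta$net_type, FUN = seq_along))
  meta <- meta[, c("trial_id", "net_type", "strain", "resistance")]

  tracks <- purrr::map(seq_len(nrow(meta)), function(i) {
    spec <- trial_spec(
      trial_id = meta$trial_id[i], net_type = meta$net_type[i],
      strain = meta$strain[i], resistance = meta$resistance[i],
      seed = derive_seed(seed, i), ...
    )
    simulate_trial(spec, ut_params = ut_params, ol_params = ol_params)
  })
  structure(
    list(tracks = dplyr::bind_rows(tracks), trials = tibble::as_tibble(meta)),
    class = "flight_study"
  )
}

#' @export
print.flight_study <- function(x, ...) {
  cat("<flight_study>\n")
  cat(sprintf("  trials: %d (%d UT, %d OL)\n", nrow(x$trials),
              sum(x$trials$net_type == "UT"), sum(x$trials$net_type == "OL")))
  n_tracks <- nrow(dplyr::distinct(x$tracks, .data$trial_id, .data$track_id))
  cat(sprintf("  tracks: %d, positions: %d\n", n_tracks, nrow(x$tracks)))
  invisible(x)
}
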