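# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so that seeded helpers never disturb the
#' caller's random stream. All randomness in the package flows through this.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed and an index,
# kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  a <- (as.double(seed) %% 2147483647) + 1
  b <- (as.double(index) %% 2147483647) + 1
  as.integer((a * 48271 + b * 69621) %% 2147483629)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Reflect coordinates into [0, width] by triangular folding (equivalent to
# specular reflection at the boundaries).
fold_reflect <- function(z, width) {
  period <- 2 * width
  z <- z %% period
  ifelse(z > width, period - z, z)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns every track table must carry, in canonical order.
track_columns <- function() {
  c("trial_id", "track_id", "frame", "t_s", "x_mm", "y_mm", "real_flag")
}

assert_track_table <- function(tracks, arg = "tracks") {
  missing <- setdiff(track_columns(), names(tracks))
  if (length(missing) > 0) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 arg, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tracks)
}

pkg_log <- function(fmt, ..., verbose = getOption("flightnet.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
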