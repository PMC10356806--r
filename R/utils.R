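## Internal helpers: deterministic seed derivation, grid checks, trapezoids.

#' Derive a child seed from a master seed and a text label
#'
#' All randomness in the package flows from one master seed; per-animal,
#' per-cell and per-purpose streams (noise vs. saccade placement) are derived
#' deterministically so any single trial can be reproduced in isolation and so
#' that, e.g., switching saccades off does not perturb the noise stream.
#' The label is hashed with a 31-multiplier polynomial modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param label Character label naming the stream (e.g. `"animal3/noise"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "animal1/noise")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(label))) h <- (h * 31 + c) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

## Error with a consistent class so tests can assert on it.
stop_optokin <- function(msg, class = "optokin_error") {
  abort(msg, class = c(class, "optokin_error"))
}

## Check a time vector is strictly increasing and uniform (to tol seconds).
check_uniform_time <- function(time, tol = 1e-9) {
  if (length(time) < 2) return(invisible(TRUE))
  dt <- diff(time)
  if (any(dt <= 0)) stop_optokin("`time` must be strictly increasing.")
  if (max(dt) - min(dt) > tol) {
    stop_optokin(sprintf(
      "`time` must be uniformly sampled (spread of sample intervals %.3g s exceeds %.3g s).",
      max(dt) - min(dt), tol
    ))
  }
  invisible(TRUE)
}

## Infer sample rate from a uniform time vector.
infer_sample_rate <- function(time) {
  check_uniform_time(time)
  1 / mean(diff(time))
}

## Trapezoidal integral with gap skipping: masked (NA) samples are dropped and
## the integral taken between remaining neighbors using their true spacing.
trapz_gapskip <- function(time, y, keep = NULL) {
  if (!is.null(keep)) {
    time <- time[keep]
    y <- y[keep]
  }
  ok <- is.finite(y) & is.finite(time)
  time <- time[ok]
  y <- y[ok]
  if (length(y) < 2) return(NA_real_)
  sum(diff(time) * (head(y, -1) + tail(y, -1)) / 2)
}

## Central-difference derivative; one-sided at the ends.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop_optokin("Need at least 3 samples to differentiate.")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

## Zero-phase low-pass Butterworth (applied forward and backward). The signal
## is extended by odd reflection at both ends before filtering so the filter
## state is consistent with the local signal level (otherwise a trace with a
## non-zero baseline picks up large start-up transients).
lowpass <- function(x, sample_rate, cutoff_hz, order = 2) {
  nyq <- sample_rate / 2
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop_optokin(sprintf(
      "Filter cutoff (%.3g Hz) must be positive and below the Nyquist frequency (%.3g Hz).",
      cutoff_hz, nyq
    ), class = "optokin_config_error")
  }
  bf <- signal::butter(order, cutoff_hz / nyq)
  n <- length(x)
  pad <- min(n - 1, max(20, ceiling(3 * sample_rate / cutoff_hz)))
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  z <- c(front, x, back)
  ## remove the endpoint-to-endpoint line before filtering: constants and
  ## ramps pass a zero-phase Butterworth unchanged, and taking them out first
  ## leaves both ends at zero so the zero-state filter has no start-up step
  m <- length(z)
  base <- z[1] + (z[m] - z[1]) * (seq_len(m) - 1) / (m - 1)
  y <- as.numeric(signal::filtfilt(bf, z - base)) + base
  y[seq(pad + 1, pad + n)]
}

## Dilate a logical run mask by `pad` samples on each side.
dilate_mask <- function(mask, pad) {
  if (pad <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  idx <- which(mask)
  lo <- pmax(idx - pad, 1L)
  hi <- pmin(idx + pad, n)
  out <- logical(n)
  for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
  out
}

## Continuous-ish least-squares slope/intercept of y on t (plain OLS).
ols_line <- function(t, y) {
  tb <- mean(t)
  yb <- mean(y)
  vt <- sum((t - tb)^2)
  if (vt == 0) return(c(slope = NA_real_, intercept = NA_real_))
  slope <- sum((t - tb) * (y - yb)) / vt
  c(slope = slope, intercept = yb - slope * tb)
}
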