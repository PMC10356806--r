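# Shared fixture builders: small, noiseless parameter sets so individual
# tests stay fast and deterministic.

quiet_params <- function(...) {
  opto_eye_params(noise_sd = 0, saccade_rate = 0, ...)
}

# A single-duration protocol small enough for per-test simulation.
small_protocol <- function(duration_ms = 1000, n = 5, ...) {
  opto_eye_params(led_durations = duration_ms, n_repeats_per_duration = n,
                  inter_trial_gap = 1.6, lead_in = 0.5, ...)
}

# Hand-built mean profile with the columns phase_metrics() needs.
fake_mean_profile <- function(rel_time_s, mag, vel = NULL, masked = FALSE) {
  tibble::tibble(
    rel_time_s = rel_time_s,
    mag_deg = mag,
    mag_f_deg = mag,
    vel_mag_dps = if (is.null(vel)) central_diff_local(mag, mean(diff(rel_time_s))) else vel,
    masked = masked
  )
}

central_diff_local <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}
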