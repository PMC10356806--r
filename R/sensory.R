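## VOR/OKR/VVOR traces with optogenetic co-stimulation; cycle folding and
## condition subtraction.

#' Generate a synthetic sensory-paradigm eye trace
#'
#' The sensory-evoked eye movement is the horizontal sinusoid
#' `gain * table_amplitude * sin(2*pi*f*t + phase_lag)`. When an opto
#' condition is selected, the evoked-movement kernel of `params$opto` is
#' added during every half-cycle in which the sensory drive moves the eye in
#' the designated direction (naso-temporal = positive horizontal velocity),
#' with LED onset at the half-cycle boundary and the LED on for the full
#' half-cycle; the release/recovery tail runs through the opposite
#' half-cycle and is truncated at the next LED onset, so the perturbation is
#' exactly cycle-periodic and recoverable by folding.
#'
#' @param params A [sensory_params()] object.
#' @return An object of class `sensory_eye_sim`: list with `trace`
#'   (tibble `time_s`, `h_deg`, `v_deg`), `schedule` (LED epochs; zero rows
#'   when the opto condition is `"off"`), `truth` (list with the one-cycle
#'   perturbation kernel sampled on the grid, `perturbation_deg`, and the
#'   params).
#' @export
gen_sensory_eye_trace <- function(params) {
  stopifnot(inherits(params, "sensory_params"))
  fs <- params$sample_rate
  dt <- 1 / fs
  f <- params$frequency
  cycle_s <- 1 / f
  half_n <- round(cycle_s / 2 * fs)
  cycle_n <- 2 * half_n
  total_n <- params$n_cycles * cycle_n + 1
  time <- seq(0, by = dt, length.out = total_n)

  phi <- params$phase_lag * pi / 180
  base <- params$gain * params$table_amplitude * sin(2 * pi * f * time + phi)

  ## One-cycle perturbation: LED covers the designated half-cycle.
  perturb_cycle <- numeric(cycle_n)
  schedule <- tibble::tibble(trial = integer(), onset_s = numeric(),
                             offset_s = numeric(), duration_ms = numeric(),
                             kind = character(), level = numeric())
  if (params$opto_condition != "off") {
    ## Eye velocity is positive (naso-temporal) for cycle phase in
    ## (-pi/2, pi/2) of the sine argument; the half-cycle starts where
    ## velocity crosses zero upward.
    start_phase <- if (params$opto_condition == "naso-temporal") -pi / 2 else pi / 2
    ## Sample index (within a cycle, from t = 0) of the half-cycle start.
    t_start <- ((start_phase - phi) / (2 * pi * f)) %% cycle_s
    i_start <- round(t_start * fs) %% cycle_n
    t_rel_cycle <- (seq_len(cycle_n) - 1) / fs
    k <- opto_kernel_position(t_rel_cycle, params$opto, half_n / fs)
    idx <- ((i_start + seq_len(cycle_n) - 1) %% cycle_n) + 1
    perturb_cycle[idx] <- k
    onsets <- (seq_len(params$n_cycles) - 1) * cycle_n / fs + i_start / fs
    schedule <- tibble::tibble(
      trial = seq_len(params$n_cycles),
      onset_s = onsets,
      offset_s = onsets + half_n / fs,
      duration_ms = 1000 * half_n / fs,
      kind = "LED",
      level = params$opto$intensity_scale
    )
  }
  perturb <- c(rep(perturb_cycle, params$n_cycles), perturb_cycle[1])

  h <- base + perturb
  v <- numeric(total_n)

  if (params$quick_phase_rate > 0) {
    withr::with_seed(derive_seed(params$seed, "quick_phases"), {
      n_qp <- rpois(1, params$quick_phase_rate * time[total_n])
      qp_times <- sort(runif(n_qp, 0, time[total_n] - params$opto$saccade_duration))
      signs <- sample(c(-1, 1), n_qp, replace = TRUE)
    })
    for (k2 in seq_along(qp_times)) {
      i0 <- round(qp_times[k2] * fs) + 1
      i1 <- min(i0 + round(params$opto$saccade_duration * fs), total_n)
      u <- (time[i0:i1] - qp_times[k2]) / params$opto$saccade_duration
      h[i0:i1] <- h[i0:i1] +
        signs[k2] * params$opto$saccade_amp * minjerk(pmin(u, 1 - u) * 2)
    }
  }

  if (params$noise_sd > 0) {
    withr::with_seed(derive_seed(params$seed, "noise"), {
      h <- h + rnorm(total_n, 0, params$noise_sd)
      v <- v + rnorm(total_n, 0, params$noise_sd)
    })
  }

  structure(list(
    trace = tibble::tibble(time_s = time, h_deg = h, v_deg = v),
    schedule = schedule,
    truth = list(params = params,
                 perturbation_deg = perturb_cycle,
                 cycle_s = cycle_n / fs),
    params = params
  ), class = "sensory_eye_sim")
}

#' Fold a periodic trace into a phase-binned cycle average
#'
#' Samples are assigned to `n_bins` phase bins modulo the stimulus cycle;
#' quick-phase-masked samples are excluded; within each cycle the bin mean is
#' taken, and the cycle average is the mean (with SEM) across cycles.
#'
#' @param trace Tibble with `time_s` and the column named in `value`
#'   (optionally a logical `masked` column to exclude samples).
#' @param frequency Stimulus frequency, Hz.
#' @param value Column to fold (default `"h_deg"`).
#' @param n_bins Number of phase bins per cycle (default 100).
#' @param condition Label stored with the result.
#' @return An object of class `cycle_average`: tibble `bin`, `phase`
#'   (bin midpoint in `[0, 1)` cycles), `mean_deg`, `sem_deg`, `n_cycles`;
#'   attributes `frequency`, `n_bins`, `condition`.
#' @export
fold_cycles <- function(trace, frequency, value = "h_deg", n_bins = 100,
                        condition = "off") {
  stopifnot("time_s" %in% names(trace), value %in% names(trace))
  cycle_s <- 1 / frequency
  n_complete <- floor((max(trace$time_s) - min(trace$time_s)) / cycle_s + 1e-9)
  if (n_complete < 3) {
    stop_optokin("Need at least 3 complete cycles to fold.",
                 class = "optokin_insufficient_data")
  }
  t0 <- min(trace$time_s)
  d <- tibble::tibble(
    t = trace$time_s - t0,
    y = trace[[value]],
    masked = if ("masked" %in% names(trace)) trace$masked else FALSE
  ) |>
    dplyr::filter(.data$t < n_complete * cycle_s, !.data$masked) |>
    dplyr::mutate(
      cycle = floor(.data$t / cycle_s),
      phase = (.data$t %% cycle_s) / cycle_s,
      ## the 1e-9 guard keeps samples that sit exactly on a bin edge (up to
      ## floating error in the modulo) in their intended bin
      bin = pmin(floor(.data$phase * n_bins + 1e-9), n_bins - 1) + 1
    )
  out <- d |>
    dplyr::group_by(.data$cycle, .data$bin) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_deg = mean(.data$y),
      sem_deg = sd(.data$y) / sqrt(dplyr::n()),
      n_cycles = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(phase = (.data$bin - 0.5) / n_bins, .after = "bin")
  structure(out, frequency = frequency, n_bins = n_bins, condition = condition,
            class = c("cycle_average", class(out)))
}

#' Subtract the no-stimulation condition from an opto condition
#'
#' Bin-wise difference `on - off` of two cycle averages on the same
#' frequency and binning, with SEM propagated as
#' `sqrt(sem_on^2 + sem_off^2)`.
#'
#' @param on,off [fold_cycles()] results for the opto and no-opto conditions.
#' @return A tibble of class `condition_difference`: `bin`, `phase`,
#'   `diff_deg`, `sem_deg`; attributes `frequency`, `conditions`.
#' @export
subtract_conditions <- function(on, off) {
  stopifnot(inherits(on, "cycle_average"), inherits(off, "cycle_average"))
  if (!isTRUE(all.equal(attr(on, "frequency"), attr(off, "frequency"))) ||
      attr(on, "n_bins") != attr(off, "n_bins")) {
    stop_optokin("Conditions differ in frequency or binning; cannot align.",
                 class = "optokin_alignment_error")
  }
  out <- tibble::tibble(
    bin = on$bin,
    phase = on$phase,
    diff_deg = on$mean_deg - off$mean_deg,
    sem_deg = sqrt(on$sem_deg^2 + off$sem_deg^2)
  )
  structure(out, frequency = attr(on, "frequency"),
            conditions = c(attr(on, "condition"), attr(off, "condition")),
            class = c("condition_difference", class(out)))
}

#' Fundamental-frequency gain and phase of a reflex trace
#'
#' Convenience summary: fits `y ~ sin + cos` at the stimulus frequency and
#' reports the response amplitude relative to the table amplitude (gain) and
#' the phase of the eye relative to the stimulus (deg).
#'
#' @param trace Tibble with `time_s` and the column in `value`.
#' @param frequency Stimulus frequency, Hz.
#' @param table_amplitude Stimulus amplitude, deg.
#' @param value Column to fit.
#' @return One-row tibble: `gain`, `phase_deg`, `amplitude_deg`.
#' @export
reflex_gain_phase <- function(trace, frequency, table_amplitude,
                              value = "h_deg") {
  s <- sin(2 * pi * frequency * trace$time_s)
  c_ <- cos(2 * pi * frequency * trace$time_s)
  fit <- lm(trace[[value]] ~ s + c_)
  a <- coef(fit)[["s"]]
  b <- coef(fit)[["c_"]]
  amp <- sqrt(a^2 + b^2)
  tibble::tibble(
    gain = amp / table_amplitude,
    phase_deg = atan2(b, a) * 180 / pi,
    amplitude_deg = amp
  )
}
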