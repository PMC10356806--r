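#' Parameters for the optogenetic eye-movement generator
#'
#' Describes the generative kernel for an optogenetically evoked eye movement:
#' during the LED epoch the magnitude position rises as a saturating
#' exponential (the fast "drive" component, asymptote `drive_amp`, time
#' constant `drive_tau`) plus a linear creep (`hold_velocity`); after LED
#' offset a fast exponential "release" of amplitude `release_amp` (time
#' constant `release_tau`) collapses onto a slow "recovery" exponential
#' (time constant `recovery_tau`) that decays back to zero. The 2-D movement
#' is this scalar kernel projected on `direction` (horizontal naso-temporal
#' positive, vertical downward negative), with white Gaussian measurement
#' noise and Poisson-timed quick phases (saccades) superimposed.
#'
#' @param sample_rate Sampling rate in Hz (default 1000; the video rate of the
#'   emulated tracker is a free choice, see the methods vignette).
#' @param led_durations LED epoch durations in ms.
#' @param n_repeats_per_duration Number of consecutive stimulations per
#'   duration (the emulated protocol uses 60).
#' @param inter_trial_gap Gap from LED offset to the next onset, in s.
#' @param lead_in Quiet time before the first onset, in s.
#' @param drive_amp Fast-component asymptote, deg.
#' @param drive_tau Fast-component time constant, s.
#' @param hold_velocity Slow creep during the LED, deg/s.
#' @param release_amp Fast release amplitude after LED offset, deg (capped at
#'   the position reached at offset so the kernel cannot undershoot zero).
#' @param release_tau Release time constant, s.
#' @param recovery_tau Recovery time constant, s.
#' @param direction Unit 2-vector (horizontal, vertical); horizontal
#'   naso-temporal positive, vertical downward negative. Normalized if needed.
#' @param intensity_scale LED intensity as a fraction in (0, 1]; scales the
#'   whole kernel.
#' @param noise_sd SD of white Gaussian measurement noise per axis, deg.
#' @param saccade_rate Poisson rate of quick phases, Hz.
#' @param saccade_amp Quick-phase excursion amplitude, deg.
#' @param saccade_duration Total duration of the out-and-back quick-phase
#'   transient, s.
#' @param seed Integer seed for this trace.
#' @return An object of class `opto_eye_params` (a validated list).
#' @export
#' @examples
#' p <- opto_eye_params(led_durations = 1000, n_repeats_per_duration = 5)
#' p$drive_amp
opto_eye_params <- function(sample_rate = 1000,
                            led_durations = c(50, 100, 200, 500, 1000),
                            n_repeats_per_duration = 60,
                            inter_trial_gap = 2,
                            lead_in = 1,
                            drive_amp = 2.5,
                            drive_tau = 0.1,
                            hold_velocity = 0.5,
                            release_amp = 2,
                            release_tau = 0.1,
                            recovery_tau = 0.35,
                            direction = c(2, -1) / sqrt(5),
                            intensity_scale = 1,
                            noise_sd = 0.1,
                            saccade_rate = 0.5,
                            saccade_amp = 3,
                            saccade_duration = 0.02,
                            seed = 1L) {
  p <- list(
    sample_rate = sample_rate, led_durations = led_durations,
    n_repeats_per_duration = n_repeats_per_duration,
    inter_trial_gap = inter_trial_gap, lead_in = lead_in,
    drive_amp = drive_amp, drive_tau = drive_tau,
    hold_velocity = hold_velocity, release_amp = release_amp,
    release_tau = release_tau, recovery_tau = recovery_tau,
    direction = direction, intensity_scale = intensity_scale,
    noise_sd = noise_sd, saccade_rate = saccade_rate,
    saccade_amp = saccade_amp, saccade_duration = saccade_duration,
    seed = as.integer(seed)
  )
  validate_opto_eye_params(p)
}

validate_opto_eye_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(p$sample_rate) || p$sample_rate <= 0) {
    stop_optokin("`sample_rate` must be a single positive number.",
                 class = "optokin_param_error")
  }
  for (tau in c("drive_tau", "release_tau", "recovery_tau")) {
    if (!num1(p[[tau]]) || p[[tau]] <= 0) {
      stop_optokin(sprintf("`%s` must be a single positive number.", tau),
                   class = "optokin_param_error")
    }
  }
  for (nm in c("drive_amp", "hold_velocity", "release_amp", "noise_sd",
               "saccade_rate", "saccade_amp", "saccade_duration",
               "inter_trial_gap", "lead_in")) {
    if (!num1(p[[nm]]) || p[[nm]] < 0) {
      stop_optokin(sprintf("`%s` must be a single non-negative number.", nm),
                   class = "optokin_param_error")
    }
  }
  if (!num1(p$intensity_scale) || p$intensity_scale <= 0 || p$intensity_scale > 1) {
    stop_optokin("`intensity_scale` must be in (0, 1].",
                 class = "optokin_param_error")
  }
  if (length(p$direction) != 2 || !all(is.finite(p$direction)) ||
      sum(p$direction^2) == 0) {
    stop_optokin("`direction` must be a finite non-zero 2-vector.",
                 class = "optokin_param_error")
  }
  p$direction <- p$direction / sqrt(sum(p$direction^2))
  if (!is.numeric(p$led_durations) || length(p$led_durations) < 1 ||
      any(p$led_durations <= 0)) {
    stop_optokin("`led_durations` must be positive (ms).",
                 class = "optokin_param_error")
  }
  structure(p, class = "opto_eye_params")
}

#' @export
print.opto_eye_params <- function(x, ...) {
  cat("<opto_eye_params>\n")
  cat(sprintf("  kernel: drive %.2f deg (tau %.0f ms) + hold %.2f deg/s; release %.2f deg (tau %.0f ms); recovery tau %.0f ms\n",
              x$drive_amp, 1000 * x$drive_tau, x$hold_velocity,
              x$release_amp, 1000 * x$release_tau, 1000 * x$recovery_tau))
  cat(sprintf("  schedule: {%s} ms x %d, gap %.1f s, fs %g Hz, intensity %.2f\n",
              paste(x$led_durations, collapse = ", "),
              x$n_repeats_per_duration, x$inter_trial_gap, x$sample_rate,
              x$intensity_scale))
  cat(sprintf("  noise %.3g deg, saccades %.2g Hz x %.1f deg, seed %d\n",
              x$noise_sd, x$saccade_rate, x$saccade_amp, x$seed))
  invisible(x)
}

#' Parameters for the sensory-paradigm (VOR/OKR/VVOR) generator
#'
#' The sensory-evoked eye movement is a sinusoid
#' `gain * table_amplitude * sin(2*pi*frequency*t + phase_lag)` on the
#' horizontal axis. When `opto_condition` is not `"off"`, the optogenetic
#' kernel of `opto` is added during every half-cycle in which the sensory
#' drive moves the eye in the designated direction (naso-temporal = positive
#' horizontal velocity), with LED onset at the half-cycle boundary and the
#' LED on for the full half-cycle; release/recovery run through the opposite
#' half-cycle and are tiled periodically.
#'
#' @param paradigm One of `"VOR"`, `"OKR"`, `"VVOR"` (label only; the three
#'   paradigms share the trace model).
#' @param frequency Stimulus frequency in Hz, within `[0.1, 1.0]`.
#' @param gain Dimensionless reflex gain (>= 0).
#' @param phase_lag Phase of the eye relative to the table/drum, deg.
#' @param table_amplitude Stimulus amplitude, deg.
#' @param opto_condition `"off"`, `"naso-temporal"` or `"temporo-nasal"`.
#' @param opto An [opto_eye_params()] object used as the perturbation kernel
#'   (its schedule fields are ignored; its kernel and noise fields are not).
#' @param n_cycles Number of stimulus cycles (>= 1).
#' @param sample_rate Sampling rate, Hz.
#' @param noise_sd SD of white Gaussian measurement noise per axis, deg.
#' @param quick_phase_rate Poisson rate of quick phases, Hz.
#' @param seed Integer seed.
#' @return An object of class `sensory_params`.
#' @export
sensory_params <- function(paradigm = c("VOR", "OKR", "VVOR"),
                           frequency = 0.6,
                           gain = 0.8,
                           phase_lag = 0,
                           table_amplitude = 5,
                           opto_condition = c("off", "naso-temporal", "temporo-nasal"),
                           opto = opto_eye_params(),
                           n_cycles = 10,
                           sample_rate = 1000,
                           noise_sd = 0.1,
                           quick_phase_rate = 0,
                           seed = 1L) {
  paradigm <- match.arg(paradigm)
  opto_condition <- match.arg(opto_condition)
  if (!is.numeric(frequency) || length(frequency) != 1 ||
      frequency < 0.1 || frequency > 1.0) {
    stop_optokin("`frequency` must be in [0.1, 1.0] Hz.",
                 class = "optokin_param_error")
  }
  if (!is.numeric(gain) || gain < 0) {
    stop_optokin("`gain` must be >= 0.", class = "optokin_param_error")
  }
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop_optokin("`n_cycles` must be >= 1.", class = "optokin_param_error")
  }
  stopifnot(inherits(opto, "opto_eye_params"))
  structure(list(
    paradigm = paradigm, frequency = frequency, gain = gain,
    phase_lag = phase_lag, table_amplitude = table_amplitude,
    opto_condition = opto_condition, opto = opto,
    n_cycles = as.integer(n_cycles), sample_rate = sample_rate,
    noise_sd = noise_sd, quick_phase_rate = quick_phase_rate,
    seed = as.integer(seed)
  ), class = "sensory_params")
}

#' Parameters for the gamma-renewal spike-train generator
#'
#' Spike trains are drawn from a gamma renewal process via time rescaling:
#' unit-mean gamma interval increments (shape `gamma_shape`, so shape 1 is
#' Poisson and large shapes approach clockwork regularity) accumulate in
#' rescaled time `Lambda(t) = integral of the intensity`, where the intensity
#' is `base_rate` outside stimulation epochs and `stim_factor * base_rate`
#' inside them.
#'
#' @param base_rate Baseline firing rate, Hz (> 0).
#' @param stim_factor Rate multiplier during epochs (>= 0; 3 emulates the
#'   excited-cell archetype, 0.25 the 75%-suppressed archetype).
#' @param gamma_shape Regularity control (> 0; 1 = Poisson).
#' @param epoch_schedule Tibble/data frame with columns `onset_s` and
#'   `duration_ms`, or NULL for no stimulation.
#' @param total_duration Recording length, s.
#' @param seed Integer seed.
#' @return An object of class `spike_gen_params`.
#' @export
spike_gen_params <- function(base_rate = 60,
                             stim_factor = 3,
                             gamma_shape = 4,
                             epoch_schedule = NULL,
                             total_duration = 60,
                             seed = 1L) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(base_rate) || base_rate <= 0) {
    stop_optokin("`base_rate` must be > 0 Hz.", class = "optokin_param_error")
  }
  if (!num1(stim_factor) || stim_factor < 0) {
    stop_optokin("`stim_factor` must be >= 0.", class = "optokin_param_error")
  }
  if (!num1(gamma_shape) || gamma_shape <= 0) {
    stop_optokin("`gamma_shape` must be > 0.", class = "optokin_param_error")
  }
  if (!num1(total_duration) || total_duration <= 0) {
    stop_optokin("`total_duration` must be > 0 s.", class = "optokin_param_error")
  }
  if (!is.null(epoch_schedule)) {
    epoch_schedule <- tibble::as_tibble(epoch_schedule)
    stopifnot(all(c("onset_s", "duration_ms") %in% names(epoch_schedule)))
    if (any(epoch_schedule$onset_s < 0) ||
        any(epoch_schedule$onset_s + epoch_schedule$duration_ms / 1000 > total_duration)) {
      stop_optokin("Epochs must lie within [0, total_duration].",
                   class = "optokin_param_error")
    }
  }
  structure(list(
    base_rate = base_rate, stim_factor = stim_factor,
    gamma_shape = gamma_shape, epoch_schedule = epoch_schedule,
    total_duration = total_duration, seed = as.integer(seed)
  ), class = "spike_gen_params")
}
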