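## Calibration, velocity profiles, quick-phase removal, cycle QC, averaging.

#' Convert raw tracker frames to calibrated angular eye position
#'
#' Applies the standard angular conversion for a video eye tracker with a
#' corneal-reflection reference: the pupil-minus-corneal-reflection offset is
#' centered (by default on its session median) and converted to degrees via
#' `asin(delta / Rp)`, where `Rp` is the radius of pupil rotation.
#'
#' @param raw Data frame with columns `time_s`, `pupil_h`, `pupil_v`,
#'   `cr_h`, `cr_v` (pupil and corneal-reflection positions in the same
#'   linear camera units as `Rp`).
#' @param Rp Radius of pupil rotation (> 0), same units as the positions.
#' @param offset Length-2 numeric `(h, v)` reference offset, or `NULL`
#'   (default) to use the per-axis session median.
#' @return A tibble `time_s`, `h_deg`, `v_deg`.
#' @export
#' @examples
#' raw <- tibble::tibble(time_s = 0:4 / 1000, pupil_h = 0.5, pupil_v = 0,
#'                       cr_h = 0, cr_v = 0)
#' calibrate_position(raw, Rp = 1, offset = c(0, 0))
calibrate_position <- function(raw, Rp, offset = NULL) {
  stopifnot(all(c("time_s", "pupil_h", "pupil_v", "cr_h", "cr_v") %in% names(raw)))
  if (!is.numeric(Rp) || length(Rp) != 1 || !is.finite(Rp) || Rp <= 0) {
    stop_optokin("`Rp` must be a single positive number.",
                 class = "optokin_param_error")
  }
  dh <- raw$pupil_h - raw$cr_h
  dv <- raw$pupil_v - raw$cr_v
  bad <- which(abs(dh) >= Rp | abs(dv) >= Rp)
  if (length(bad) > 0) {
    stop_optokin(sprintf(
      "Pupil-CR offset reaches or exceeds Rp at frame %d (and %d more): outside the calibration range.",
      bad[1], length(bad) - 1L
    ), class = "optokin_calibration_error")
  }
  if (is.null(offset)) offset <- c(median(dh), median(dv))
  rh <- (dh - offset[1]) / Rp
  rv <- (dv - offset[2]) / Rp
  bad <- which(abs(rh) >= 1 | abs(rv) >= 1)
  if (length(bad) > 0) {
    stop_optokin(sprintf(
      "Offset-corrected pupil-CR displacement reaches Rp at frame %d: outside the calibration range.",
      bad[1]
    ), class = "optokin_calibration_error")
  }
  tibble::tibble(
    time_s = raw$time_s,
    h_deg = asin(rh) * 180 / pi,
    v_deg = asin(rv) * 180 / pi
  )
}

#' Magnitude eye position
#'
#' Scalar displacement `sqrt(h^2 + v^2)` used for all phase metrics.
#'
#' @param h,v Horizontal and vertical position, deg.
#' @return Numeric vector of magnitudes, deg.
#' @export
eye_magnitude <- function(h, v) sqrt(h^2 + v^2)

#' Compute a cleaned velocity profile from an eye-position trace
#'
#' Differentiates the position signal (central differences, one-sided at the
#' endpoints) and applies a zero-phase low-pass Butterworth filter; the same
#' is repeated on the velocity to obtain acceleration. The magnitude channel
#' is low-pass filtered first and then differentiated (`mag_f_deg`,
#' `vel_mag_dps`); since differentiation and LTI filtering commute this
#' equals filtering the raw derivative, and it makes the trapezoidal integral
#' of `vel_mag_dps` agree with the endpoint displacement of `mag_f_deg` by
#' construction (see the methods vignette).
#'
#' @param trace Data frame with a time column (`time_s` or `rel_time_s`),
#'   `h_deg` and `v_deg`. Time must be uniform.
#' @param cutoff_hz Low-pass cutoff, Hz (must be below Nyquist).
#' @param order Butterworth order (applied forward and backward).
#' @return The input tibble with added columns `mag_deg`, `mag_f_deg`,
#'   `vel_h_dps`, `vel_v_dps`, `vel_mag_dps`, `speed_dps`
#'   (`sqrt(vel_h^2 + vel_v^2)`, used for quick-phase detection),
#'   `acc_mag_dps2`, and a `masked` column initialized to `FALSE`. Filter
#'   settings are recorded in attribute `"filter_cfg"`.
#' @export
compute_velocity <- function(trace, cutoff_hz = 50, order = 2) {
  time_col <- intersect(c("time_s", "rel_time_s"), names(trace))[1]
  if (is.na(time_col)) stop_optokin("`trace` needs a `time_s` or `rel_time_s` column.")
  stopifnot(all(c("h_deg", "v_deg") %in% names(trace)))
  if (nrow(trace) < 5) stop_optokin("Need at least 5 samples.")
  if (!all(is.finite(trace$h_deg)) || !all(is.finite(trace$v_deg))) {
    stop_optokin("`h_deg` and `v_deg` must be finite.")
  }
  time <- trace[[time_col]]
  fs <- infer_sample_rate(time)
  dt <- 1 / fs

  out <- tibble::as_tibble(trace)
  out$mag_deg <- eye_magnitude(out$h_deg, out$v_deg)
  out$mag_f_deg <- lowpass(out$mag_deg, fs, cutoff_hz, order)
  out$vel_h_dps <- lowpass(central_diff(out$h_deg, dt), fs, cutoff_hz, order)
  out$vel_v_dps <- lowpass(central_diff(out$v_deg, dt), fs, cutoff_hz, order)
  out$vel_mag_dps <- central_diff(out$mag_f_deg, dt)
  out$speed_dps <- sqrt(out$vel_h_dps^2 + out$vel_v_dps^2)
  out$acc_mag_dps2 <- lowpass(central_diff(out$vel_mag_dps, dt), fs, cutoff_hz, order)
  if (!"masked" %in% names(out)) out$masked <- FALSE
  attr(out, "filter_cfg") <- list(cutoff_hz = cutoff_hz, order = order,
                                  sample_rate = fs, type = "butterworth zero-phase")
  out
}

#' Mask fast eye-movement components (quick phases / saccades)
#'
#' Samples whose 2-D eye speed exceeds `threshold` are flagged in the
#' `masked` column, padded by `pad_ms` on each side to remove saccade
#' shoulders. Position values are untouched; downstream averages and fits
#' exclude masked samples.
#'
#' @param profile Output of [compute_velocity()].
#' @param threshold Speed threshold, deg/s (default 40; `Inf` masks nothing).
#' @param pad_ms Padding applied around each supra-threshold run, ms.
#' @return `profile` with an updated logical `masked` column.
#' @export
remove_fast_phases <- function(profile, threshold = 40, pad_ms = 10) {
  stopifnot("speed_dps" %in% names(profile))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    stop_optokin("`threshold` must be a single positive number (deg/s).",
                 class = "optokin_config_error")
  }
  fs <- attr(profile, "filter_cfg")$sample_rate
  if (is.null(fs)) {
    time_col <- intersect(c("time_s", "rel_time_s"), names(profile))[1]
    fs <- infer_sample_rate(profile[[time_col]])
  }
  fast <- profile$speed_dps > threshold
  pad <- round(pad_ms / 1000 * fs)
  profile$masked <- (if ("masked" %in% names(profile)) profile$masked else FALSE) |
    dilate_mask(fast, pad)
  profile
}

#' Cut a continuous trace into stimulus-aligned cycles
#'
#' @param profile Output of [compute_velocity()] (optionally after
#'   [remove_fast_phases()]), with a `time_s` column.
#' @param schedule Stimulus schedule tibble with `onset_s`, `offset_s` and
#'   (optionally) `duration_ms`, `trial`.
#' @param pre_s Window kept before each onset, s.
#' @param post_s Window kept after each offset, s.
#' @return A long tibble with columns `trial`, `duration_ms`, `rel_time_s`
#'   (time relative to LED onset, on the sample grid) plus all data columns.
#' @export
extract_cycles <- function(profile, schedule, pre_s = 0.2, post_s = 1.2) {
  stopifnot("time_s" %in% names(profile))
  fs <- infer_sample_rate(profile$time_s)
  t0 <- profile$time_s[1]
  n <- nrow(profile)
  if (!"trial" %in% names(schedule)) schedule$trial <- seq_len(nrow(schedule))
  if (!"duration_ms" %in% names(schedule)) {
    schedule$duration_ms <- round((schedule$offset_s - schedule$onset_s) * 1000)
  }
  purrr::pmap_dfr(schedule[c("trial", "onset_s", "offset_s", "duration_ms")],
    function(trial, onset_s, offset_s, duration_ms) {
      i_on <- round((onset_s - t0) * fs) + 1
      i0 <- max(1L, i_on - round(pre_s * fs))
      i1 <- min(n, round((offset_s - t0) * fs) + 1 + round(post_s * fs))
      chunk <- profile[i0:i1, , drop = FALSE]
      chunk$rel_time_s <- (seq(i0, i1) - i_on) / fs
      chunk$trial <- trial
      chunk$duration_ms <- duration_ms
      chunk
    })
}

#' Quality-control individual cycles
#'
#' A cycle is included when (1) the eye was steady in the `pre_window_s`
#' before stimulation (SD of the magnitude position at most
#' `steadiness_deg`), and (2) the magnitude position crossed a movement
#' threshold during stimulation: any unmasked in-stimulation sample exceeding
#' the pre-window mean plus twice the pre-window SD. The SD in criterion (2)
#' is floored at `sd_floor_deg` so a noiseless flat trace cannot trivially
#' cross its own threshold.
#'
#' @param cycles Output of [extract_cycles()].
#' @param pre_window_s Length of the pre-stimulation window, s (default 20 ms).
#' @param steadiness_deg Ceiling on the pre-window magnitude-position SD, deg.
#' @param sd_floor_deg Floor on the SD used in the crossing criterion, deg.
#' @return A tibble with one row per cycle: `trial`, `duration_ms`,
#'   `included`, `reason` (`"ok"`, `"short_pre"`, `"unsteady"`,
#'   `"no_crossing"`), `pre_mean_deg`, `pre_sd_deg`.
#' @export
qc_cycles <- function(cycles, pre_window_s = 0.02, steadiness_deg = 0.25,
                      sd_floor_deg = 0.01) {
  stopifnot(all(c("trial", "rel_time_s", "mag_deg", "masked", "duration_ms")
                %in% names(cycles)))
  fs <- 1 / mean(diff(sort(unique(cycles$rel_time_s))))
  need <- floor(pre_window_s * fs)
  cycles |>
    dplyr::group_by(.data$trial, .data$duration_ms) |>
    dplyr::group_modify(function(d, key) {
      pre <- d$mag_deg[d$rel_time_s >= -pre_window_s & d$rel_time_s < 0]
      if (length(pre) < need) {
        return(tibble::tibble(included = FALSE, reason = "short_pre",
                              pre_mean_deg = NA_real_, pre_sd_deg = NA_real_))
      }
      pre_mean <- mean(pre)
      pre_sd <- sd(pre)
      if (pre_sd > steadiness_deg) {
        return(tibble::tibble(included = FALSE, reason = "unsteady",
                              pre_mean_deg = pre_mean, pre_sd_deg = pre_sd))
      }
      stim <- d$rel_time_s >= 0 & d$rel_time_s <= key$duration_ms / 1000 & !d$masked
      crossed <- any(d$mag_deg[stim] >
                       pre_mean + 2 * max(pre_sd, sd_floor_deg))
      tibble::tibble(
        included = crossed,
        reason = if (crossed) "ok" else "no_crossing",
        pre_mean_deg = pre_mean, pre_sd_deg = pre_sd
      )
    }) |>
    dplyr::ungroup()
}

#' Average included cycles into a mean response
#'
#' Pointwise mean of the horizontal and vertical position over included
#' cycles, excluding masked samples (mask holes shrink the per-point n; they
#' are never interpolated into the average). The magnitude of the mean trace
#' is recomputed from the averaged axes.
#'
#' @param cycles Output of [extract_cycles()].
#' @param qc Optional output of [qc_cycles()]; when given, only included
#'   cycles are averaged.
#' @return A tibble per `duration_ms` and `rel_time_s`: `h_deg`, `v_deg`,
#'   `mag_deg`, `n_cycles` (unmasked cycles contributing), `all_masked`.
#' @export
average_cycles <- function(cycles, qc = NULL) {
  if (!is.null(qc)) {
    keep <- qc$trial[qc$included]
    cycles <- cycles[cycles$trial %in% keep, , drop = FALSE]
  }
  if (nrow(cycles) == 0) {
    stop_optokin("No included cycles to average.", class = "optokin_empty_error")
  }
  cycles |>
    dplyr::group_by(.data$duration_ms, .data$rel_time_s) |>
    dplyr::summarise(
      h_deg = mean(.data$h_deg[!.data$masked]),
      v_deg = mean(.data$v_deg[!.data$masked]),
      n_cycles = sum(!.data$masked),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mag_deg = eye_magnitude(.data$h_deg, .data$v_deg),
      all_masked = .data$n_cycles == 0
    )
}

#' Average per-animal mean responses into a group mean with SEM
#'
#' @param animal_means Long tibble of per-animal mean traces with columns
#'   `animal_id`, `rel_time_s` and the value columns in `cols`.
#' @param cols Value columns to average.
#' @return A tibble per `rel_time_s` with, for each value column, its
#'   pointwise group mean (same name), SEM (`<name>_sem`) and `n_animals`.
#' @export
average_animals <- function(animal_means,
                            cols = intersect(c("h_deg", "v_deg", "mag_deg",
                                               "vel_mag_dps"),
                                             names(animal_means))) {
  stopifnot(all(c("animal_id", "rel_time_s") %in% names(animal_means)))
  if (dplyr::n_distinct(animal_means$animal_id) < 2) {
    stop_optokin("Need at least 2 animals for a group SEM.")
  }
  animal_means |>
    dplyr::group_by(.data$rel_time_s) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sem = ~sd(.x, na.rm = TRUE) / sqrt(sum(is.finite(.x))))),
      n_animals = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~sub("_mean$", "", .x), dplyr::ends_with("_mean"))
}

#' Normalize a mean magnitude trace to its value 100 ms after LED onset
#'
#' @param mean_trace Tibble with `rel_time_s` and `mag_deg` (e.g. from
#'   [average_cycles()]).
#' @param at_s Normalization time after onset, s (default 0.1).
#' @param floor Numeric floor below which normalization is refused.
#' @return `mean_trace` with an added `mag_norm` column (exactly 1 at the
#'   normalization sample).
#' @export
normalize_position <- function(mean_trace, at_s = 0.1, floor = 1e-6) {
  stopifnot(all(c("rel_time_s", "mag_deg") %in% names(mean_trace)))
  i <- which.min(abs(mean_trace$rel_time_s - at_s))
  ref <- mean_trace$mag_deg[i]
  if (!is.finite(ref) || abs(ref) < floor) {
    stop_optokin(sprintf(
      "Magnitude at onset + %g ms (%.3g deg) is below the normalization floor.",
      1000 * at_s, ref
    ), class = "optokin_normalization_error")
  }
  mean_trace$mag_norm <- mean_trace$mag_deg / ref
  mean_trace
}

#' Full per-animal kinematics: velocity, masking, QC, cycle average
#'
#' Convenience wrapper running the whole per-animal pipeline for one LED
#' duration: [compute_velocity()] on the raw trace,
#' [remove_fast_phases()], [extract_cycles()], [qc_cycles()],
#' [average_cycles()], then a velocity profile of the mean trace. Samples of
#' the mean trace where every cycle was masked are linearly interpolated
#' only so the zero-phase filter has a contiguous signal, and stay flagged
#' `masked` so fits and integrals exclude them.
#'
#' @param sim An `opto_eye_sim` (or a list with `trace` and `schedule`).
#' @param duration_ms LED duration to analyze (must appear in the schedule).
#' @param threshold,pad_ms Quick-phase removal settings
#'   ([remove_fast_phases()]).
#' @param cutoff_hz,order Velocity filter settings ([compute_velocity()]).
#' @param pre_s,post_s Cycle window ([extract_cycles()]).
#' @param ... Passed to [qc_cycles()].
#' @return A list of class `animal_response`: `mean` (velocity profile of the
#'   mean trace, with `rel_time_s`), `qc`, `n_included`, `duration_ms`.
#' @export
animal_mean_response <- function(sim, duration_ms, threshold = 40, pad_ms = 10,
                                 cutoff_hz = 50, order = 2,
                                 pre_s = 0.2, post_s = 1.2, ...) {
  schedule <- sim$schedule[sim$schedule$duration_ms == duration_ms, , drop = FALSE]
  if (nrow(schedule) == 0) {
    stop_optokin(sprintf("No %g-ms epochs in the schedule.", duration_ms))
  }
  prof <- compute_velocity(sim$trace, cutoff_hz = cutoff_hz, order = order) |>
    remove_fast_phases(threshold = threshold, pad_ms = pad_ms)
  cyc <- extract_cycles(prof, schedule, pre_s = pre_s, post_s = post_s)
  qc <- qc_cycles(cyc, ...)
  avg <- average_cycles(cyc, qc)

  ## Filter needs a gap-free signal: interpolate all-masked holes, keep them
  ## flagged so downstream fits drop them again.
  for (col in c("h_deg", "v_deg")) {
    y <- avg[[col]]
    if (anyNA(y)) {
      ok <- is.finite(y)
      avg[[col]] <- approx(avg$rel_time_s[ok], y[ok], xout = avg$rel_time_s,
                           rule = 2)$y
    }
  }
  mean_prof <- compute_velocity(avg, cutoff_hz = cutoff_hz, order = order)
  mean_prof$masked <- avg$all_masked

  structure(list(
    mean = mean_prof,
    qc = qc,
    n_included = sum(qc$included),
    duration_ms = duration_ms
  ), class = "animal_response")
}

#' @export
print.animal_response <- function(x, ...) {
  cat(sprintf("<animal_response> %g-ms LED, %d/%d cycles included\n",
              x$duration_ms, x$n_included, nrow(x$qc)))
  invisible(x)
}
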