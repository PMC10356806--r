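## Four-phase decomposition (drive / hold / release / recovery) and metrics.

#' Segment an evoked movement into kinematic phases
#'
#' The drive and release phases are the first `drive_s` / `release_s`
#' (default 100 ms) after LED onset and offset respectively; the hold phase
#' spans from the end of the drive phase to LED offset; the recovery phase is
#' the first full second after the end of the release phase. Movements evoked
#' by LEDs shorter than `min_four_phase_ms` are decomposed into drive and
#' release only, with `four_phase = FALSE` flagged.
#'
#' @param onset_s,offset_s LED onset and offset, s.
#' @param trace_end_s End of the available trace, s (for the truncation flag).
#' @param drive_s,release_s,recovery_s Phase durations, s.
#' @param min_four_phase_ms Minimum LED duration for the four-phase
#'   decomposition, ms (default 200).
#' @return A tibble of class `phase_segmentation` with columns `phase`
#'   (`drive`, `hold`, `release`, `recovery`), `start_s`, `end_s`; attributes
#'   `four_phase` and `truncated_recovery`.
#' @export
#' @examples
#' segment_phases(0, 1)
segment_phases <- function(onset_s, offset_s, trace_end_s = offset_s + 1.1,
                           drive_s = 0.1, release_s = 0.1, recovery_s = 1.0,
                           min_four_phase_ms = 200) {
  duration <- offset_s - onset_s
  if (duration <= 0) stop_optokin("LED offset must follow onset.")
  four_phase <- duration * 1000 >= min_four_phase_ms
  if (four_phase) {
    seg <- tibble::tibble(
      phase = factor(c("drive", "hold", "release", "recovery"),
                     levels = c("drive", "hold", "release", "recovery")),
      start_s = c(onset_s, onset_s + drive_s, offset_s, offset_s + release_s),
      end_s = c(onset_s + drive_s, offset_s, offset_s + release_s,
                offset_s + release_s + recovery_s)
    )
  } else {
    seg <- tibble::tibble(
      phase = factor(c("drive", "release"),
                     levels = c("drive", "hold", "release", "recovery")),
      start_s = c(onset_s, offset_s),
      end_s = c(onset_s + min(drive_s, duration), offset_s + release_s)
    )
  }
  truncated <- trace_end_s < max(seg$end_s)
  if (truncated) {
    warn(sprintf(
      "Trace ends %.3f s before the end of the recovery phase; recovery metrics will be truncated.",
      max(seg$end_s) - trace_end_s
    ))
    seg$end_s <- pmin(seg$end_s, trace_end_s)
  }
  structure(seg, four_phase = four_phase, truncated_recovery = truncated,
            class = c("phase_segmentation", class(seg)))
}

#' Per-phase kinematic metrics of a mean evoked movement
#'
#' For each phase, an ordinary least-squares line of the magnitude eye
#' position against time over unmasked samples gives the phase mean velocity
#' (slope) and starting position (fit evaluated at the phase start); the net
#' distance traveled is the trapezoidal area under the magnitude velocity
#' profile, skipping masked samples (integration bridges the gap between the
#' unmasked neighbors). Trace-level summaries: the maximum amplitude is the
#' (filtered) magnitude at the LED-offset sample, and the initial peak
#' velocity is the largest unmasked magnitude velocity inside the drive
#' window.
#'
#' @param mean_profile A mean-trace velocity profile (e.g.
#'   `animal_mean_response()$mean`) with `rel_time_s`, `mag_deg`,
#'   `mag_f_deg`, `vel_mag_dps`, `masked`.
#' @param seg A [segment_phases()] result (on the same relative time base,
#'   onset at 0).
#' @param min_samples Minimum unmasked samples for a phase fit (default 3);
#'   phases with fewer get `NA` metrics and a flag.
#' @return An object of class `phase_fit`: list with `phases` (tibble:
#'   `phase`, `start_s`, `end_s`, `n`, `mean_velocity_dps`,
#'   `start_position_deg`, `net_distance_deg`, `flag`) and `trace` (tibble:
#'   `max_amplitude_deg`, `initial_peak_velocity_dps`, `offset_masked`).
#'   Retrieve them with [tidy()] and [glance()].
#' @export
phase_metrics <- function(mean_profile, seg, min_samples = 3) {
  stopifnot(all(c("rel_time_s", "mag_deg", "mag_f_deg", "vel_mag_dps", "masked")
                %in% names(mean_profile)))
  stopifnot(inherits(seg, "phase_segmentation"))
  tt <- mean_profile$rel_time_s
  dt <- mean(diff(tt))

  phases <- purrr::pmap_dfr(seg[c("phase", "start_s", "end_s")],
    function(phase, start_s, end_s) {
      inwin <- tt >= start_s - dt / 2 & tt <= end_s + dt / 2
      keep <- inwin & !mean_profile$masked
      n <- sum(keep)
      if (n < min_samples) {
        return(tibble::tibble(phase = phase, start_s = start_s, end_s = end_s,
                              n = n, mean_velocity_dps = NA_real_,
                              start_position_deg = NA_real_,
                              net_distance_deg = NA_real_,
                              flag = "too_few_samples"))
      }
      fit <- ols_line(tt[keep], mean_profile$mag_deg[keep])
      tibble::tibble(
        phase = phase, start_s = start_s, end_s = end_s, n = n,
        mean_velocity_dps = unname(fit["slope"]),
        start_position_deg = unname(fit["intercept"] + fit["slope"] * start_s),
        net_distance_deg = trapz_gapskip(tt[inwin],
                                         mean_profile$vel_mag_dps[inwin],
                                         keep = !mean_profile$masked[inwin]),
        flag = "ok"
      )
    })

  offset_s <- seg$end_s[seg$phase == "hold"]
  if (length(offset_s) == 0) offset_s <- seg$start_s[seg$phase == "release"]
  metrics <- trace_level_metrics(mean_profile, seg, offset_s)

  structure(list(phases = phases, trace = metrics, segmentation = seg),
            class = "phase_fit")
}

trace_level_metrics <- function(mean_profile, seg, offset_s) {
  tt <- mean_profile$rel_time_s
  i_off <- which.min(abs(tt - offset_s))
  offset_masked <- mean_profile$masked[i_off]
  if (offset_masked) {
    ok <- which(!mean_profile$masked)
    i_off <- ok[which.min(abs(tt[ok] - offset_s))]
  }
  drive <- seg[seg$phase == "drive", ]
  in_drive <- tt >= drive$start_s & tt <= drive$end_s & !mean_profile$masked
  tibble::tibble(
    max_amplitude_deg = mean_profile$mag_f_deg[i_off],
    initial_peak_velocity_dps = if (any(in_drive)) {
      max(mean_profile$vel_mag_dps[in_drive])
    } else NA_real_,
    offset_masked = offset_masked
  )
}

#' Maximum amplitude of the evoked movement
#'
#' The magnitude eye position at the moment the LED turns off (the nearest
#' unmasked sample if the offset sample is masked).
#'
#' @inheritParams phase_metrics
#' @return Amplitude in degrees.
#' @export
max_amplitude <- function(mean_profile, seg) {
  offset_s <- seg$start_s[seg$phase == "release"]
  trace_level_metrics(mean_profile, seg, offset_s)$max_amplitude_deg
}

#' Initial peak velocity of the evoked movement
#'
#' Largest unmasked magnitude velocity within the drive window ("shortly
#' after LED onset").
#'
#' @inheritParams phase_metrics
#' @return Peak velocity in deg/s.
#' @export
initial_peak_velocity <- function(mean_profile, seg) {
  offset_s <- seg$start_s[seg$phase == "release"]
  trace_level_metrics(mean_profile, seg, offset_s)$initial_peak_velocity_dps
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit>\n")
  print(x$phases)
  cat(sprintf("max amplitude %.3f deg, initial peak velocity %.2f deg/s\n",
              x$trace$max_amplitude_deg, x$trace$initial_peak_velocity_dps))
  invisible(x)
}
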