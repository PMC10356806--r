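## Synthetic optogenetic eye-movement traces with closed-form ground truth.

#' Evaluate the evoked-movement kernel (magnitude position)
#'
#' Closed form of the generative kernel for a single LED epoch, as a function
#' of time relative to LED onset. During the LED the magnitude rises as
#' `s * (drive_amp * (1 - exp(-t/drive_tau)) + hold_velocity * t)`; after
#' offset a fast release exponential of amplitude `min(s * release_amp, M_off)`
#' collapses onto a slow recovery exponential that decays to zero, where
#' `M_off` is the position reached at offset and `s` is `intensity_scale`.
#'
#' @param t_rel Time relative to LED onset, s (vectorized; negative times
#'   return 0).
#' @param params An [opto_eye_params()] object.
#' @param duration_s LED duration in seconds.
#' @return Magnitude eye position in degrees.
#' @export
opto_kernel_position <- function(t_rel, params, duration_s) {
  s <- params$intensity_scale
  during <- function(t) {
    s * (params$drive_amp * (1 - exp(-t / params$drive_tau)) +
           params$hold_velocity * t)
  }
  m_off <- during(duration_s)
  rel_eff <- min(s * params$release_amp, m_off)
  plateau <- m_off - rel_eff
  out <- numeric(length(t_rel))
  on <- t_rel >= 0 & t_rel <= duration_s
  post <- t_rel > duration_s
  out[on] <- during(t_rel[on])
  d <- t_rel[post] - duration_s
  out[post] <- rel_eff * exp(-d / params$release_tau) +
    plateau * exp(-d / params$recovery_tau)
  out
}

#' Evaluate the evoked-movement kernel velocity (analytic derivative)
#'
#' @inheritParams opto_kernel_position
#' @return Magnitude eye velocity in deg/s.
#' @export
opto_kernel_velocity <- function(t_rel, params, duration_s) {
  s <- params$intensity_scale
  m_off <- s * (params$drive_amp * (1 - exp(-duration_s / params$drive_tau)) +
                  params$hold_velocity * duration_s)
  rel_eff <- min(s * params$release_amp, m_off)
  plateau <- m_off - rel_eff
  out <- numeric(length(t_rel))
  on <- t_rel >= 0 & t_rel <= duration_s
  post <- t_rel > duration_s
  out[on] <- s * (params$drive_amp / params$drive_tau *
                    exp(-t_rel[on] / params$drive_tau) + params$hold_velocity)
  d <- t_rel[post] - duration_s
  out[post] <- -rel_eff / params$release_tau * exp(-d / params$release_tau) -
    plateau / params$recovery_tau * exp(-d / params$recovery_tau)
  out
}

#' Closed-form per-phase ground truth for an evoked movement
#'
#' Computes, for each kinematic phase (drive, hold, release, recovery, using
#' the same boundaries as [segment_phases()]), the least-squares slope of the
#' noiseless analytic kernel over the phase window (the estimand of the
#' per-phase linear fit), the net displacement (kernel value at phase end
#' minus phase start), and the endpoint-based mean velocity
#' (net displacement / phase duration). The slope is evaluated on a dense
#' grid at the parameterized sample rate, so it is a property of the kernel
#' alone, independent of noise, filtering or masking.
#'
#' @inheritParams opto_kernel_position
#' @param drive_s,release_s,recovery_s Phase durations in s (defaults 0.1,
#'   0.1 and 1.0).
#' @return A tibble with one row per phase: `phase`, `start_s`, `end_s`,
#'   `mean_velocity_dps` (LS slope), `endpoint_velocity_dps`,
#'   `net_displacement_deg`.
#' @export
opto_kernel_truth <- function(params, duration_s,
                              drive_s = 0.1, release_s = 0.1, recovery_s = 1.0) {
  seg <- segment_phases(onset_s = 0, offset_s = duration_s,
                        trace_end_s = duration_s + release_s + recovery_s,
                        drive_s = drive_s, release_s = release_s,
                        recovery_s = recovery_s)
  dt <- 1 / params$sample_rate
  purrr::pmap_dfr(seg[c("phase", "start_s", "end_s")], function(phase, start_s, end_s) {
    tt <- seq(start_s, end_s, by = dt)
    m <- opto_kernel_position(tt, params, duration_s)
    fit <- ols_line(tt, m)
    tibble::tibble(
      phase = phase, start_s = start_s, end_s = end_s,
      mean_velocity_dps = unname(fit["slope"]),
      endpoint_velocity_dps = (m[length(m)] - m[1]) / (end_s - start_s),
      net_displacement_deg = m[length(m)] - m[1]
    )
  })
}

## Min-jerk position profile on [0, 1].
minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Generate a synthetic optogenetically evoked eye-movement trace
#'
#' Builds the LED schedule (each duration repeated
#' `n_repeats_per_duration` times, consecutive trials separated by
#' `inter_trial_gap`), evaluates the evoked kernel for every epoch, projects
#' the scalar kernel on the 2-D `direction`, and superimposes Poisson-timed
#' out-and-back quick phases and white measurement noise. Noise and quick
#' phases draw from independently derived seed streams, so regenerating with
#' `saccade_rate = 0` leaves the noise realization unchanged.
#'
#' @param params An [opto_eye_params()] object.
#' @return An object of class `opto_eye_sim`: a list with
#'   \describe{
#'     \item{trace}{tibble `time_s`, `h_deg`, `v_deg`}
#'     \item{schedule}{tibble `trial`, `onset_s`, `offset_s`, `duration_ms`,
#'       `kind`, `level`}
#'     \item{truth}{list with per-duration phase ground truth
#'       ([opto_kernel_truth()]), true saccade times, and the params}
#'   }
#' @export
#' @examples
#' sim <- gen_opto_eye_trace(opto_eye_params(
#'   led_durations = 200, n_repeats_per_duration = 3, noise_sd = 0
#' ))
#' head(sim$trace)
gen_opto_eye_trace <- function(params) {
  stopifnot(inherits(params, "opto_eye_params"))
  params <- validate_opto_eye_params(params)
  fs <- params$sample_rate
  dt <- 1 / fs
  snap <- function(t) round(t * fs) / fs

  durations <- rep(params$led_durations, each = params$n_repeats_per_duration)
  onsets <- numeric(length(durations))
  t_cursor <- params$lead_in
  for (k in seq_along(durations)) {
    onsets[k] <- snap(t_cursor)
    t_cursor <- onsets[k] + durations[k] / 1000 + params$inter_trial_gap
  }
  schedule <- tibble::tibble(
    trial = seq_along(durations),
    onset_s = onsets,
    offset_s = snap(onsets + durations / 1000),
    duration_ms = durations,
    kind = "LED",
    level = params$intensity_scale
  )

  total_s <- snap(t_cursor)
  time <- seq(0, total_s, by = dt)
  n <- length(time)
  m <- numeric(n)
  bounds <- c(schedule$onset_s, total_s + dt)
  for (k in seq_len(nrow(schedule))) {
    i0 <- round(schedule$onset_s[k] * fs) + 1
    i1 <- min(round(bounds[k + 1] * fs), n)
    idx <- i0:i1
    m[idx] <- opto_kernel_position(time[idx] - schedule$onset_s[k], params,
                                   durations[k] / 1000)
  }

  saccade_times <- numeric(0)
  sac <- numeric(n)
  if (params$saccade_rate > 0 && params$saccade_amp > 0) {
    withr::with_seed(derive_seed(params$seed, "saccades"), {
      n_sac <- rpois(1, params$saccade_rate * total_s)
      saccade_times <- sort(runif(n_sac, 0, total_s - params$saccade_duration))
      signs <- sample(c(-1, 1), n_sac, replace = TRUE)
    })
    half <- params$saccade_duration / 2
    for (k in seq_along(saccade_times)) {
      i0 <- round(saccade_times[k] * fs) + 1
      i1 <- min(i0 + round(params$saccade_duration * fs), n)
      u <- (time[i0:i1] - saccade_times[k]) / params$saccade_duration
      shape <- minjerk(pmin(u, 1 - u) * 2)
      sac[i0:i1] <- sac[i0:i1] + signs[k] * params$saccade_amp * shape
    }
  }

  scalar <- m + sac
  h <- params$direction[1] * scalar
  v <- params$direction[2] * scalar
  if (params$noise_sd > 0) {
    withr::with_seed(derive_seed(params$seed, "noise"), {
      h <- h + rnorm(n, 0, params$noise_sd)
      v <- v + rnorm(n, 0, params$noise_sd)
    })
  }

  truth <- list(
    params = params,
    phase_truth = purrr::map(
      stats::setNames(as.list(unique(params$led_durations)),
                      paste0("ms", unique(params$led_durations))),
      function(d) opto_kernel_truth(params, d / 1000)
    ),
    saccade_times = saccade_times
  )

  structure(list(
    trace = tibble::tibble(time_s = time, h_deg = h, v_deg = v),
    schedule = schedule,
    truth = truth,
    params = params
  ), class = "opto_eye_sim")
}

#' @export
print.opto_eye_sim <- function(x, ...) {
  cat(sprintf("<opto_eye_sim> %d samples at %g Hz, %d LED epochs, %d quick phases\n",
              nrow(x$trace), x$params$sample_rate, nrow(x$schedule),
              length(x$truth$saccade_times)))
  invisible(x)
}

#' Generate a synthetic cohort of animals from genotype archetypes
#'
#' Each group is defined by an archetype [opto_eye_params()]; per-animal
#' kinematic parameters (`drive_amp`, `drive_tau`, `hold_velocity`,
#' `release_amp`, `release_tau`, `recovery_tau`) are jittered around the
#' archetype with multiplicative log-normal noise of SD `jitter_sd` (keeping
#' them positive), and every animal gets a deterministically derived seed so
#' any single animal is reproducible in isolation.
#'
#' @param archetypes Named list of [opto_eye_params()] objects, one per group.
#' @param n_animals Integer vector of animals per group (recycled; each >= 2).
#' @param jitter_sd SD of the log-normal parameter jitter (0 = identical
#'   parameters within a group).
#' @param seed Master seed.
#' @param dir Optional directory: when given, per-animal trace and schedule
#'   files plus a ground-truth manifest are written there (see
#'   [write_eye_trace()], [write_manifest()]).
#' @return An object of class `opto_cohort`: a tibble with one row per animal
#'   (`animal_id`, `group`, `seed`, list-columns `params` and `sim`), with the
#'   manifest list attached as attribute `"manifest"`.
#' @export
gen_cohort <- function(archetypes, n_animals, jitter_sd = 0.1, seed = 1L,
                       dir = NULL) {
  if (length(archetypes) == 0) {
    stop_optokin("`archetypes` must name at least one group.",
                 class = "optokin_param_error")
  }
  if (is.null(names(archetypes)) || any(names(archetypes) == "")) {
    stop_optokin("`archetypes` must be a named list.",
                 class = "optokin_param_error")
  }
  n_animals <- rep_len(as.integer(n_animals), length(archetypes))
  if (any(n_animals < 2)) {
    stop_optokin("Each group needs at least 2 animals.",
                 class = "optokin_param_error")
  }

  jitter_fields <- c("drive_amp", "drive_tau", "hold_velocity",
                     "release_amp", "release_tau", "recovery_tau")
  rows <- purrr::imap(archetypes, function(arch, group) {
    stopifnot(inherits(arch, "opto_eye_params"))
    ng <- n_animals[[match(group, names(archetypes))]]
    purrr::map(seq_len(ng), function(i) {
      id <- sprintf("%s_%02d", group, i)
      aseed <- derive_seed(seed, paste0("animal/", id))
      p <- arch
      if (jitter_sd > 0) {
        withr::with_seed(derive_seed(seed, paste0("jitter/", id)), {
          for (f in jitter_fields) {
            p[[f]] <- p[[f]] * exp(rnorm(1, 0, jitter_sd))
          }
        })
      }
      p$seed <- aseed
      p <- validate_opto_eye_params(p)
      list(animal_id = id, group = group, seed = aseed, params = p)
    })
  })
  rows <- purrr::flatten(rows)

  cohort <- tibble::tibble(
    animal_id = purrr::map_chr(rows, "animal_id"),
    group = purrr::map_chr(rows, "group"),
    seed = purrr::map_int(rows, "seed"),
    params = purrr::map(rows, "params"),
    sim = purrr::map(rows, function(r) gen_opto_eye_trace(r$params))
  )

  manifest <- list(
    master_seed = as.integer(seed),
    jitter_sd = jitter_sd,
    groups = names(archetypes),
    animals = purrr::pmap(cohort[c("animal_id", "group", "seed", "params")],
      function(animal_id, group, seed, params) {
        list(
          animal_id = animal_id, group = group, seed = seed,
          params = params[c("drive_amp", "drive_tau", "hold_velocity",
                            "release_amp", "release_tau", "recovery_tau",
                            "intensity_scale", "noise_sd", "saccade_rate",
                            "saccade_amp", "sample_rate")]
        )
      })
  )
  attr(cohort, "manifest") <- manifest
  class(cohort) <- c("opto_cohort", class(cohort))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::pwalk(cohort[c("animal_id", "sim")], function(animal_id, sim) {
      write_eye_trace(sim$trace, file.path(dir, paste0(animal_id, "_trace.csv")))
      write_schedule(sim$schedule, file.path(dir, paste0(animal_id, "_schedule.csv")))
    })
    write_manifest(manifest, file.path(dir, "manifest.yaml"))
  }
  cohort
}
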