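## End-to-end reproducible run: simulate -> kinematics -> phases ->
## divergence -> spikes -> sensory, with a machine-readable report.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: quick-phase threshold 40 deg/s,
#' 20-ms QC pre-window, 100-ms drive/release phases, alpha 0.05, 5-ms PSTH
#' bins. The default cohort is deliberately small (two archetypes, 3 animals
#' each, 10 repeats of 200- and 1000-ms LEDs) so a full run completes in
#' seconds; scale it up through the config.
#'
#' @param seed Master seed for the whole run.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = c("simulate", "kinematics", "phases", "divergence", "spikes",
               "sensory"),
    cohort = list(
      groups = list(
        fast_large = list(drive_amp = 2.5, drive_tau = 0.1,
                          hold_velocity = 0.5, release_amp = 2),
        slow_small = list(drive_amp = 1.2, drive_tau = 0.18,
                          hold_velocity = 0.25, release_amp = 1)
      ),
      n_animals = c(3, 3),
      jitter_sd = 0.1,
      led_durations = c(200, 1000),
      n_repeats_per_duration = 10,
      noise_sd = 0.1,
      saccade_rate = 0.5
    ),
    kinematics = list(threshold = 40, pad_ms = 10, cutoff_hz = 50, order = 2,
                      pre_window_s = 0.02, steadiness_deg = 0.25,
                      sd_floor_deg = 0.01),
    phases = list(drive_s = 0.1, release_s = 0.1, recovery_s = 1.0,
                  min_four_phase_ms = 200),
    divergence = list(alpha = 0.05, duration_ms = 1000),
    spikes = list(n_cells = 6, base_rate = 60, gamma_shape = 4,
                  stim_factors = c(3, 0.25), n_epochs = 30, peri_ms = 200,
                  bin_ms = 5, up_thr = 1.5, down_thr = 0.5),
    sensory = list(frequency = 0.6, gain = 0.8, table_amplitude = 5,
                   n_cycles = 10, n_bins = 100)
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding both default and file.
#' @return A `run_config` list.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the selected stages: cohort simulation, per-animal kinematics and
#' QC, per-phase metrics for every animal and LED duration, the pointwise
#' between-group t-score map, spike-train epoch responses with
#' classification, and the sensory-paradigm subtraction. Writes delimited
#' tables, a JSON report and a run log (with every resolved parameter and
#' seed) to `out_dir` when given.
#'
#' @param config A `run_config` list ([default_config()] / [read_config()]).
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_report` with elements `phase_metrics`,
#'   `qc`, `divergence`, `spikes`, `sensory`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  cfg <- config
  stages <- cfg$stages
  report <- list(config = cfg)

  archetypes <- purrr::imap(cfg$cohort$groups, function(overrides, nm) {
    do.call(opto_eye_params, c(
      overrides,
      list(led_durations = cfg$cohort$led_durations,
           n_repeats_per_duration = cfg$cohort$n_repeats_per_duration,
           noise_sd = cfg$cohort$noise_sd,
           saccade_rate = cfg$cohort$saccade_rate)
    ))
  })
  cohort <- gen_cohort(archetypes, cfg$cohort$n_animals,
                       jitter_sd = cfg$cohort$jitter_sd,
                       seed = derive_seed(cfg$seed, "cohort"))
  report$cohort_manifest <- attr(cohort, "manifest")

  if (any(c("kinematics", "phases", "divergence") %in% stages)) {
    k <- cfg$kinematics
    responses <- purrr::pmap(cohort[c("animal_id", "group", "sim")],
      function(animal_id, group, sim) {
        purrr::map(cfg$cohort$led_durations, function(d) {
          resp <- animal_mean_response(
            sim, d, threshold = k$threshold, pad_ms = k$pad_ms,
            cutoff_hz = k$cutoff_hz, order = k$order,
            pre_window_s = k$pre_window_s,
            steadiness_deg = k$steadiness_deg, sd_floor_deg = k$sd_floor_deg
          )
          list(animal_id = animal_id, group = group, duration_ms = d,
               resp = resp)
        })
      }) |> purrr::flatten()

    report$qc <- purrr::map_dfr(responses, function(r) {
      dplyr::mutate(r$resp$qc, animal_id = r$animal_id, group = r$group,
                    .before = 1)
    })

    if ("phases" %in% stages) {
      ph <- cfg$phases
      report$phase_metrics <- purrr::map_dfr(responses, function(r) {
        seg <- segment_phases(
          0, r$duration_ms / 1000,
          trace_end_s = max(r$resp$mean$rel_time_s),
          drive_s = ph$drive_s, release_s = ph$release_s,
          recovery_s = ph$recovery_s, min_four_phase_ms = ph$min_four_phase_ms
        )
        fit <- phase_metrics(r$resp$mean, seg)
        dplyr::mutate(
          tidy(fit),
          animal_id = r$animal_id, group = r$group,
          duration_ms = r$duration_ms,
          four_phase = attr(seg, "four_phase"),
          max_amplitude_deg = fit$trace$max_amplitude_deg,
          initial_peak_velocity_dps = fit$trace$initial_peak_velocity_dps,
          .before = 1
        )
      })
    }

    if ("divergence" %in% stages) {
      dcfg <- cfg$divergence
      vel_long <- purrr::map_dfr(
        purrr::keep(responses, ~.x$duration_ms == dcfg$duration_ms),
        function(r) {
          tibble::tibble(animal_id = r$animal_id, group = r$group,
                         rel_time_s = r$resp$mean$rel_time_s,
                         vel_mag_dps = r$resp$mean$vel_mag_dps)
        })
      report$divergence <- pointwise_tscore(vel_long, alpha = dcfg$alpha)
    }
  }

  if ("spikes" %in% stages) {
    s <- cfg$spikes
    onsets <- 1 + (seq_len(s$n_epochs) - 1) * 2
    epochs <- tibble::tibble(onset_s = onsets, duration_ms = s$peri_ms)
    total <- max(onsets) + 2
    report$spikes <- purrr::map_dfr(seq_len(s$n_cells), function(i) {
      fac <- s$stim_factors[(i - 1) %% length(s$stim_factors) + 1]
      st <- gen_spike_train(spike_gen_params(
        base_rate = s$base_rate, stim_factor = fac,
        gamma_shape = s$gamma_shape, epoch_schedule = epochs,
        total_duration = total,
        seed = derive_seed(cfg$seed, paste0("cell/", i))
      ))
      resp <- epoch_response(st$spikes, onsets, peri_s = s$peri_ms / 1000,
                             bin_s = s$bin_ms / 1000)
      tibble::tibble(
        cell = sprintf("cell_%02d", i),
        true_factor = fac,
        baseline_hz = length(st$spikes) / total,
        cv2 = cv2(st$spikes),
        normalized_peri = resp$summary$normalized_peri,
        class = as.character(classify_response(resp, s$up_thr, s$down_thr))
      )
    })
  }

  if ("sensory" %in% stages) {
    sn <- cfg$sensory
    mk <- function(cond, tag) gen_sensory_eye_trace(sensory_params(
      frequency = sn$frequency, gain = sn$gain,
      table_amplitude = sn$table_amplitude, n_cycles = sn$n_cycles,
      opto_condition = cond, noise_sd = cfg$cohort$noise_sd,
      seed = derive_seed(cfg$seed, paste0("sensory/", tag))
    ))
    sim_on <- mk("naso-temporal", "on")
    sim_off <- mk("off", "off")
    fold_on <- fold_cycles(sim_on$trace, sn$frequency, n_bins = sn$n_bins,
                           condition = "naso-temporal")
    fold_off <- fold_cycles(sim_off$trace, sn$frequency, n_bins = sn$n_bins,
                            condition = "off")
    report$sensory <- subtract_conditions(fold_on, fold_off)
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$phase_metrics)) {
    cat(sprintf("  phase metrics: %d rows (%d animals)\n",
                nrow(x$phase_metrics),
                dplyr::n_distinct(x$phase_metrics$animal_id)))
  }
  if (!is.null(x$divergence)) {
    cat(sprintf("  divergence: %d/%d points significant\n",
                sum(x$divergence$significant), nrow(x$divergence)))
  }
  if (!is.null(x$spikes)) {
    cat(sprintf("  spikes: %d cells (%s)\n", nrow(x$spikes),
                paste(table(x$spikes$class), collapse = "/")))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(dplyr::mutate(df, dplyr::across(
      dplyr::where(is.numeric), ~round(.x, 10))),
      file.path(out_dir, name))
  }
  if (!is.null(report$phase_metrics)) wr(report$phase_metrics, "phase_metrics.csv")
  if (!is.null(report$qc)) wr(report$qc, "qc.csv")
  if (!is.null(report$divergence)) {
    wr(tibble::as_tibble(report$divergence), "divergence.csv")
  }
  if (!is.null(report$spikes)) wr(report$spikes, "spike_summary.csv")
  if (!is.null(report$sensory)) {
    wr(tibble::as_tibble(report$sensory), "sensory_difference.csv")
  }
  summary <- list(
    seed = report$config$seed,
    stages = report$config$stages,
    n_phase_rows = if (!is.null(report$phase_metrics)) nrow(report$phase_metrics) else 0L,
    significant_points = if (!is.null(report$divergence)) sum(report$divergence$significant) else NULL,
    spike_classes = if (!is.null(report$spikes)) as.list(table(report$spikes$class)) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(list(config = unclass(report$config)),
                 file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
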