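## Gamma-renewal spike generator and peri-stimulus / ex vivo spike analyses.

#' Generate a spike train from a rate-modulated gamma renewal process
#'
#' Uses time rescaling: unit-mean gamma increments (shape `gamma_shape`,
#' rate `gamma_shape`) are accumulated in rescaled time
#' `Lambda(t) = integral r(s) ds`, where the intensity `r` equals
#' `base_rate` outside the stimulation epochs and `stim_factor * base_rate`
#' inside them; spike times are the increments mapped back through the
#' (piecewise-linear) inverse of `Lambda`. Shape 1 gives a Poisson process;
#' large shapes approach a clockwork train.
#'
#' @param params A [spike_gen_params()] object.
#' @return An object of class `spike_train_sim`: list with `spikes` (sorted
#'   numeric vector of spike times in s), `epochs` (the schedule tibble or
#'   NULL), `truth` (list: `base_rate`, `stim_factor`, expected counts per
#'   epoch), `params`.
#' @export
#' @examples
#' st <- gen_spike_train(spike_gen_params(base_rate = 50, total_duration = 10))
#' length(st$spikes)
gen_spike_train <- function(params) {
  stopifnot(inherits(params, "spike_gen_params"))
  T_total <- params$total_duration
  ep <- params$epoch_schedule

  ## Knots of the piecewise-linear cumulative intensity Lambda(t).
  if (is.null(ep) || nrow(ep) == 0 || params$stim_factor == 1) {
    t_knots <- c(0, T_total)
    r_seg <- params$base_rate
  } else {
    ep <- ep[order(ep$onset_s), , drop = FALSE]
    on <- ep$onset_s
    off <- ep$onset_s + ep$duration_ms / 1000
    t_knots <- unique(sort(c(0, on, off, T_total)))
    mids <- head(t_knots, -1) + diff(t_knots) / 2
    in_epoch <- vapply(mids, function(m) any(m >= on & m < off), logical(1))
    r_seg <- ifelse(in_epoch, params$stim_factor * params$base_rate,
                    params$base_rate)
  }
  lam_knots <- c(0, cumsum(r_seg * diff(t_knots)))
  lam_total <- lam_knots[length(lam_knots)]
  if (lam_total <= 0) {
    stop_optokin("Total intensity is zero; no spikes can be generated.",
                 class = "optokin_param_error")
  }

  spikes_rescaled <- withr::with_seed(derive_seed(params$seed, "spikes"), {
    acc <- numeric(0)
    last <- 0
    while (last < lam_total) {
      n_draw <- max(100, ceiling((lam_total - last) * 1.2) + 50)
      inc <- rgamma(n_draw, shape = params$gamma_shape,
                    rate = params$gamma_shape)
      acc <- c(acc, last + cumsum(inc))
      last <- acc[length(acc)]
    }
    acc[acc <= lam_total]
  })

  ## Invert Lambda; flat segments (stim_factor = 0) have zero hit probability.
  keep <- !duplicated(lam_knots)
  spikes <- approx(lam_knots[keep], t_knots[keep], xout = spikes_rescaled)$y
  spikes <- sort(spikes[is.finite(spikes)])

  truth <- list(
    base_rate = params$base_rate,
    stim_factor = params$stim_factor,
    expected_epoch_count = if (!is.null(ep) && nrow(ep) > 0) {
      params$stim_factor * params$base_rate * ep$duration_ms / 1000
    } else numeric(0)
  )
  structure(list(spikes = spikes, epochs = ep, truth = truth, params = params),
            class = "spike_train_sim")
}

#' @export
print.spike_train_sim <- function(x, ...) {
  cat(sprintf("<spike_train_sim> %d spikes over %g s (%.1f Hz), %d epochs\n",
              length(x$spikes), x$params$total_duration,
              length(x$spikes) / x$params$total_duration,
              if (is.null(x$epochs)) 0L else nrow(x$epochs)))
  invisible(x)
}

#' Mean firing rate in a window
#'
#' @param spikes Sorted spike times, s.
#' @param t0,t1 Window `[t0, t1)`, s.
#' @return Rate in Hz (spike count / window length).
#' @export
firing_rate <- function(spikes, t0, t1) {
  if (t1 <= t0) stop_optokin("`t1` must exceed `t0`.")
  sum(spikes >= t0 & spikes < t1) / (t1 - t0)
}

#' CV2: local interspike-interval variability
#'
#' Mean over consecutive interspike-interval pairs of
#' `2 * |ISI[i+1] - ISI[i]| / (ISI[i+1] + ISI[i])`. CV2 is 0 for a perfectly
#' regular train and 1 in expectation for a Poisson process; unlike the
#' plain CV it is insensitive to slow rate drift.
#'
#' @param spikes Sorted spike times, s (at least 3 spikes).
#' @return CV2 (dimensionless), or `NA` with a warning when fewer than
#'   3 spikes are supplied.
#' @export
cv2 <- function(spikes) {
  if (length(spikes) < 3) {
    warn("CV2 undefined for fewer than 3 spikes; returning NA.")
    return(NA_real_)
  }
  isi <- diff(spikes)
  a <- head(isi, -1)
  b <- tail(isi, -1)
  mean(2 * abs(b - a) / (b + a))
}

#' Peri-stimulus epoch response of a spike train
#'
#' Each stimulation epoch is analyzed in a 2-s window tiled exactly as
#' `pre_s` of pre-stimulation, `peri_s` of stimulation, and the remaining
#' post-stimulation time. Per-epoch and averaged pre/peri/post firing rates
#' are computed; the peri rate normalized to the pre rate is the modulation
#' index; and the PSTH is the mean spike count per `bin_s` bin across all
#' stimulations, aligned to stimulus onset.
#'
#' @param spikes Sorted spike times, s.
#' @param onsets Stimulation onset times, s.
#' @param peri_s Stimulation (peri) window length, s (e.g. 0.05, 0.1, 0.2).
#' @param pre_s Pre-stimulation window, s (default 0.5).
#' @param total_s Total epoch window, s (default 2; post = total - pre - peri).
#' @param bin_s PSTH bin width, s (default 0.005).
#' @return An object of class `epoch_response`: list with `per_epoch`
#'   (tibble: `epoch`, `pre_hz`, `peri_hz`, `post_hz`, `normalized_peri`),
#'   `summary` (one-row tibble with mean rates, `normalized_peri` =
#'   mean peri rate / mean pre rate, and a `pre_rate_zero` flag), and `psth`
#'   (tibble: `bin_start_s` relative to onset, `mean_count`).
#' @export
epoch_response <- function(spikes, onsets, peri_s, pre_s = 0.5, total_s = 2,
                           bin_s = 0.005) {
  post_s <- total_s - pre_s - peri_s
  if (post_s <= 0) stop_optokin("`total_s` must exceed `pre_s + peri_s`.")
  if (length(onsets) < 1) stop_optokin("Need at least one epoch onset.")
  if (min(onsets) - pre_s < 0) {
    stop_optokin("First epoch does not leave room for the pre-stimulation window.")
  }

  per_epoch <- purrr::map_dfr(seq_along(onsets), function(k) {
    on <- onsets[k]
    pre <- firing_rate(spikes, on - pre_s, on)
    peri <- firing_rate(spikes, on, on + peri_s)
    post <- firing_rate(spikes, on + peri_s, on + peri_s + post_s)
    tibble::tibble(
      epoch = k, pre_hz = pre, peri_hz = peri, post_hz = post,
      normalized_peri = if (pre > 0) peri / pre else NA_real_
    )
  })

  pre_mean <- mean(per_epoch$pre_hz)
  summary <- tibble::tibble(
    n_epochs = nrow(per_epoch),
    pre_hz = pre_mean,
    peri_hz = mean(per_epoch$peri_hz),
    post_hz = mean(per_epoch$post_hz),
    normalized_peri = if (pre_mean > 0) mean(per_epoch$peri_hz) / pre_mean else NA_real_,
    pre_rate_zero = pre_mean == 0
  )
  if (summary$pre_rate_zero) {
    warn("Pre-stimulation rate is zero; normalized peri rate undefined.")
  }

  ## integer-multiple bin edges (a plain seq() accumulates rounding error,
  ## which misplaces spikes that land exactly on a window boundary)
  breaks <- seq(-round(pre_s / bin_s), round((peri_s + post_s) / bin_s)) * bin_s
  counts <- matrix(0, nrow = length(onsets), ncol = length(breaks) - 1)
  for (k in seq_along(onsets)) {
    rel <- spikes[spikes >= onsets[k] - pre_s &
                    spikes < onsets[k] + peri_s + post_s] - onsets[k]
    if (length(rel) > 0) {
      counts[k, ] <- tabulate(findInterval(rel, breaks), length(breaks) - 1)
    }
  }
  psth <- tibble::tibble(
    bin_start_s = head(breaks, -1),
    mean_count = colMeans(counts)
  )

  structure(list(per_epoch = per_epoch, summary = summary, psth = psth,
                 windows = list(pre_s = pre_s, peri_s = peri_s,
                                post_s = post_s, bin_s = bin_s)),
            class = "epoch_response")
}

#' @export
print.epoch_response <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<epoch_response> %d epochs: pre %.1f Hz, peri %.1f Hz (normalized %.2f), post %.1f Hz\n",
              s$n_epochs, s$pre_hz, s$peri_hz, s$normalized_peri, s$post_hz))
  invisible(x)
}

#' Classify a cell's stimulation response
#'
#' @param normalized_peri Normalized peri-stimulation rate (peri / pre), from
#'   [epoch_response()] (a `epoch_response` object is also accepted).
#' @param up_thr Threshold at or above which the cell is `excited`
#'   (default 1.5).
#' @param down_thr Threshold at or below which the cell is `suppressed`
#'   (default 0.5).
#' @return Factor with levels `excited`, `suppressed`, `unmodulated`.
#' @export
classify_response <- function(normalized_peri, up_thr = 1.5, down_thr = 0.5) {
  if (inherits(normalized_peri, "epoch_response")) {
    normalized_peri <- normalized_peri$summary$normalized_peri
  }
  if (up_thr <= down_thr) {
    stop_optokin("`up_thr` must exceed `down_thr`.",
                 class = "optokin_config_error")
  }
  if (anyNA(normalized_peri)) {
    stop_optokin("Normalized peri rate undefined; cannot classify.")
  }
  out <- ifelse(normalized_peri >= up_thr, "excited",
                ifelse(normalized_peri <= down_thr, "suppressed", "unmodulated"))
  factor(out, levels = c("excited", "suppressed", "unmodulated"))
}

#' Input-output curve from current-injection steps
#'
#' For each injected current, counts the spikes inside the 500-ms pulse and
#' measures the latency from pulse onset to the first spike.
#'
#' @param steps Long tibble with columns `current_pA`, `sweep`, and `spike_s`
#'   (spike times relative to pulse onset, s; sweeps with no spikes may be
#'   absent or carry `NA`).
#' @param sweeps Optional tibble `current_pA`, `sweep` enumerating all
#'   delivered sweeps (so silent sweeps count toward the average); defaults
#'   to the sweeps present in `steps`.
#' @param pulse_s Pulse duration, s (default 0.5).
#' @return A tibble of class `io_curve`: per current step, `n_sweeps`,
#'   `mean_count` (spikes per pulse), `mean_latency_ms` (first-spike latency,
#'   `NA` when no sweep spiked).
#' @export
io_curve <- function(steps, sweeps = NULL, pulse_s = 0.5) {
  stopifnot(all(c("current_pA", "sweep", "spike_s") %in% names(steps)))
  if (is.null(sweeps)) {
    sweeps <- dplyr::distinct(steps[c("current_pA", "sweep")])
  }
  in_pulse <- steps |>
    dplyr::filter(is.finite(.data$spike_s), .data$spike_s >= 0,
                  .data$spike_s <= pulse_s)
  per_sweep <- in_pulse |>
    dplyr::group_by(.data$current_pA, .data$sweep) |>
    dplyr::summarise(count = dplyr::n(),
                     latency_ms = 1000 * min(.data$spike_s),
                     .groups = "drop")
  out <- sweeps |>
    dplyr::left_join(per_sweep, by = c("current_pA", "sweep")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$current_pA) |>
    dplyr::summarise(
      n_sweeps = dplyr::n(),
      mean_count = mean(.data$count),
      mean_latency_ms = if (all(is.na(.data$latency_ms))) NA_real_ else
        mean(.data$latency_ms, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$current_pA)
  class(out) <- c("io_curve", class(out))
  out
}
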