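## broom-style tidiers for the package's result objects.

#' Tidy a phase fit into one row per phase
#'
#' @param x A `phase_fit` from [phase_metrics()].
#' @param ... Unused.
#' @return Tibble with `phase`, `start_s`, `end_s`, `n`,
#'   `mean_velocity_dps`, `start_position_deg`, `net_distance_deg`, `flag`.
#' @exportS3Method generics::tidy
tidy.phase_fit <- function(x, ...) x$phases

#' One-row trace-level summary of a phase fit
#'
#' @param x A `phase_fit`.
#' @param ... Unused.
#' @return Tibble with `max_amplitude_deg`, `initial_peak_velocity_dps`,
#'   `four_phase`, `truncated_recovery`, `offset_masked`.
#' @exportS3Method generics::glance
glance.phase_fit <- function(x, ...) {
  dplyr::mutate(x$trace,
                four_phase = attr(x$segmentation, "four_phase"),
                truncated_recovery = attr(x$segmentation, "truncated_recovery"))
}

#' Tidy a pointwise t-score trace
#'
#' @param x A `tscore_trace` from [pointwise_tscore()].
#' @param ... Unused.
#' @return Plain tibble of the per-time-point results.
#' @exportS3Method generics::tidy
tidy.tscore_trace <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a t-score trace
#'
#' @param x A `tscore_trace`.
#' @param ... Unused.
#' @return Tibble with `df`, `alpha`, `critical`, `n_points`,
#'   `n_significant`, `frac_significant`, `n_degenerate`.
#' @exportS3Method generics::glance
glance.tscore_trace <- function(x, ...) {
  tibble::tibble(
    df = attr(x, "df"),
    alpha = attr(x, "alpha"),
    critical = attr(x, "critical"),
    n_points = nrow(x),
    n_significant = sum(x$significant),
    frac_significant = mean(x$significant),
    n_degenerate = sum(x$degenerate)
  )
}

#' Tidy an epoch response into one row per epoch
#'
#' @param x An `epoch_response` from [epoch_response()].
#' @param ... Unused.
#' @return The per-epoch rate tibble.
#' @exportS3Method generics::tidy
tidy.epoch_response <- function(x, ...) x$per_epoch

#' One-row summary of an epoch response
#'
#' @param x An `epoch_response`.
#' @param ... Unused.
#' @return The summary tibble (mean rates, normalized peri, flags).
#' @exportS3Method generics::glance
glance.epoch_response <- function(x, ...) x$summary

#' Tidy a cycle average
#'
#' @param x A `cycle_average` from [fold_cycles()].
#' @param ... Unused.
#' @return Plain tibble with `bin`, `phase`, `mean_deg`, `sem_deg`,
#'   `n_cycles`, plus `frequency` and `condition` columns.
#' @exportS3Method generics::tidy
tidy.cycle_average <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                frequency = attr(x, "frequency"),
                condition = attr(x, "condition"))
}
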