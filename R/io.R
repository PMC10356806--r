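## Delimited-text readers/writers (round-trip safe) and config handling.

#' Write / read an eye-position trace
#'
#' Delimited text with columns `time_s, h_deg, v_deg`.
#'
#' @param trace Tibble with `time_s`, `h_deg`, `v_deg`.
#' @param path File path.
#' @return `read_eye_trace()` returns the trace tibble.
#' @export
write_eye_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "h_deg", "v_deg") %in% names(trace)))
  readr::write_csv(trace[c("time_s", "h_deg", "v_deg")], path)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    h_deg = readr::col_double(),
    v_deg = readr::col_double()
  ))
}

#' Write / read a stimulus schedule
#'
#' Delimited text with columns `onset_s, offset_s, kind, level` (plus
#' `trial`, `duration_ms` bookkeeping columns).
#'
#' @param schedule Schedule tibble.
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(all(c("onset_s", "offset_s", "kind", "level") %in% names(schedule)))
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols())
  stopifnot(all(c("onset_s", "offset_s", "kind", "level") %in% names(out)))
  out
}

#' Write / read a spike train
#'
#' Delimited text with one spike time (s) per row; the header line carries
#' the cell label as `# cell: <label>`.
#'
#' @param spikes Numeric spike times, s.
#' @param path File path.
#' @param cell Cell label stored in the header.
#' @return `read_spike_train()` returns a list with `spikes` and `cell`.
#' @export
write_spike_train <- function(spikes, path, cell = "cell") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell: %s", cell), "spike_s",
               format(spikes, digits = 15, scientific = FALSE, trim = TRUE)),
             con)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  cell <- sub("^# cell: ", "", lines[1])
  spikes <- as.numeric(lines[-(1:2)])
  list(spikes = spikes, cell = cell)
}

#' Write / read a ground-truth manifest or run configuration (YAML)
#'
#' @param x A list (manifest or config).
#' @param path File path.
#' @return `read_manifest()` returns the list.
#' @export
write_manifest <- function(x, path) {
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}
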