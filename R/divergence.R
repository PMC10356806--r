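## Pointwise between-group t-score map and its significance threshold.

#' Two-tailed Student-t critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical value `qt(1 - alpha/2, df)`.
#' @export
#' @examples
#' critical_t(30, 0.05)
critical_t <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || length(df) != 1 || !is.finite(df) || df < 1) {
    stop_optokin("`df` must be a single number >= 1.",
                 class = "optokin_param_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_optokin("`alpha` must be in (0, 1).", class = "optokin_param_error")
  }
  qt(1 - alpha / 2, df)
}

#' Pointwise between-group |t|-score trace
#'
#' At every time point, an unpaired two-tailed Student's t test
#' (pooled variance, `df = nA + nB - 2`) compares the per-animal values of
#' the two groups; the absolute t-score is stored together with a
#' significance mask at the critical value for `alpha`. Time points with
#' zero pooled variance are reported as degenerate with `|t| = 0` rather
#' than errored (mask holes can produce them). No multiple-testing
#' correction is applied across time points.
#'
#' @param data Long tibble with one row per animal and time point.
#' @param value,time,animal,group Names of the value, time, animal-id and
#'   group columns (defaults `"vel_mag_dps"`, `"rel_time_s"`, `"animal_id"`,
#'   `"group"`). The group column must have exactly two levels, each with at
#'   least 2 animals at every time point.
#' @param alpha Two-tailed significance level.
#' @param df_override Optional integer overriding the computed degrees of
#'   freedom (some published thresholds use a different df convention).
#' @return An object of class `tscore_trace`: a tibble `time_s`, `t_abs`,
#'   `significant`, `degenerate`, `n_a`, `n_b`, with attributes `df`,
#'   `alpha`, `critical`, `groups`.
#' @export
pointwise_tscore <- function(data, value = "vel_mag_dps", time = "rel_time_s",
                             animal = "animal_id", group = "group",
                             alpha = 0.05, df_override = NULL) {
  stopifnot(all(c(value, time, animal, group) %in% names(data)))
  groups <- sort(unique(as.character(data[[group]])))
  if (length(groups) != 2) {
    stop_optokin("`group` must have exactly two levels.",
                 class = "optokin_param_error")
  }
  d <- tibble::tibble(
    time = data[[time]],
    value = data[[value]],
    grp = as.character(data[[group]])
  )
  res <- d |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      n_a = sum(.data$grp == groups[1]),
      n_b = sum(.data$grp == groups[2]),
      mean_a = mean(.data$value[.data$grp == groups[1]]),
      mean_b = mean(.data$value[.data$grp == groups[2]]),
      ss_a = sum((.data$value[.data$grp == groups[1]] -
                    mean(.data$value[.data$grp == groups[1]]))^2),
      ss_b = sum((.data$value[.data$grp == groups[2]] -
                    mean(.data$value[.data$grp == groups[2]]))^2),
      .groups = "drop"
    )
  if (any(res$n_a < 2 | res$n_b < 2)) {
    stop_optokin("Each group needs >= 2 animals at every time point.",
                 class = "optokin_param_error")
  }
  df <- if (is.null(df_override)) res$n_a + res$n_b - 2 else rep(df_override, nrow(res))
  sp2 <- (res$ss_a + res$ss_b) / (res$n_a + res$n_b - 2)
  se <- sqrt(sp2 * (1 / res$n_a + 1 / res$n_b))
  t_abs <- abs(res$mean_a - res$mean_b) / se
  degenerate <- !is.finite(t_abs)
  t_abs[degenerate] <- 0
  crit <- critical_t(df[1], alpha)

  out <- tibble::tibble(
    time_s = res$time,
    t_abs = t_abs,
    significant = t_abs > crit,
    degenerate = degenerate,
    n_a = res$n_a,
    n_b = res$n_b
  )
  structure(out, df = df[1], alpha = alpha, critical = crit, groups = groups,
            class = c("tscore_trace", class(out)))
}

#' @export
print.tscore_trace <- function(x, ...) {
  cat(sprintf("<tscore_trace> %s vs %s, df = %d, |t| > %.3f at alpha = %g; %d/%d points significant\n",
              attr(x, "groups")[1], attr(x, "groups")[2], attr(x, "df"),
              attr(x, "critical"), attr(x, "alpha"),
              sum(x$significant), nrow(x)))
  NextMethod()
}
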