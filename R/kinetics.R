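#' Enrichment rate of one subject over a fit window
#'
#' Ordinary least-squares line (free intercept by default) through the
#' (time, C5 enrichment) points falling inside the fit window; the slope is
#' the enrichment rate in fractional enrichment per minute. A through-origin
#' variant is available for sensitivity analysis. Points flagged
#' below-baseline are legitimate noise realizations near t = 0 and are not
#' excluded by this function.
#'
#' @param t Reported times, minutes.
#' @param e C5 fractional enrichments.
#' @param window Fit window `c(t0, t1)`, minutes, inclusive.
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @return Tibble: `slope`, `intercept`, `se_slope`, `sigma` (residual SD),
#'   `n`, `t0`, `t1`.
#' @examples
#' fit_rate(seq(0, 120, 10), 0.0029 * seq(0, 120, 10))
#' @export
fit_rate <- function(t, e, window = c(0, 120), through_origin = FALSE) {
  stopifnot(length(t) == length(e), length(window) == 2L)
  keep <- is.finite(t) & is.finite(e) & t >= window[1] & t <= window[2]
  t <- t[keep]; e <- e[keep]
  if (length(t) < 3L) {
    stop("need at least 3 points inside the fit window", call. = FALSE)
  }
  if (stats::var(t) == 0) {
    stop("degenerate fit: no time variance inside the window", call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(e ~ t + 0) else stats::lm(e ~ t)
  co <- summary(fit)$coefficients
  tibble::tibble(
    slope = co["t", "Estimate"],
    intercept = if (through_origin) 0 else co["(Intercept)", "Estimate"],
    se_slope = co["t", "Std. Error"],
    sigma = summary(fit)$sigma,
    n = length(t),
    t0 = window[1], t1 = window[2]
  )
}

#' Group-level summaries of per-subject enrichment rates
#'
#' Mean and standard error (SD/sqrt(n)) of the subject slopes within each
#' group, ordered by group label. Groups with a single subject yield an
#' `NA` standard error with a warning.
#'
#' @param rates Tibble with at least `group` and `slope` columns (one row
#'   per subject, e.g. from [fit_rates_table()]).
#' @return Tibble: `group`, `mean_slope`, `se_slope`, `n`.
#' @export
group_rates <- function(rates) {
  stopifnot(all(c("group", "slope") %in% names(rates)))
  out <- rates |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      se_slope = stats::sd(.data$slope) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
  if (any(out$n < 2L)) {
    warning("group(s) with n < 2: standard error undefined", call. = FALSE)
  }
  out
}
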