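#' Reported (brain-time) midpoint of a collection window
#'
#' Microdialysate takes a fixed dead time (default 180 s) to travel from the
#' probe to the collection vial, so the fluid in a vial window represents
#' brain events that happened earlier. The reported time of a fraction is
#' the window midpoint minus the dead time, in minutes from infusion start.
#' Pre-infusion fractions yield negative reported times and mark baseline.
#'
#' @param t_start,t_end Window start/end, clock minutes relative to the
#'   start of the tracer infusion. Vectorized.
#' @param dead_time_s Probe-to-vial transit time, seconds (default 180).
#' @return Reported time, minutes.
#' @examples
#' reported_time(60, 65) # 59.5
#' @export
reported_time <- function(t_start, t_end, dead_time_s = 180) {
  if (any(t_end <= t_start)) stop("window end must exceed start", call. = FALSE)
  (t_start + t_end) / 2 - dead_time_s / 60
}

#' Pool consecutive dialysate fractions
#'
#' Pools 2-3 consecutive fractions of the same subject/analyte into one, as
#' done before GC-MS when single 5-min fractions carry too little analyte:
#' the pooled window spans first start to last end, SIM peak areas add, and
#' the concentration is the volume-weighted mean (equal volumes at constant
#' flow, hence the arithmetic mean).
#'
#' @param fractions Tibble/data frame of consecutive fractions ordered by
#'   time, with columns `t_start`, `t_end`, and optionally `conc_uM`,
#'   `area_heavy`, `area_light` plus identifier columns (which must be
#'   constant and are carried through).
#' @return One-row tibble for the pooled fraction.
#' @export
pool_fractions <- function(fractions) {
  fractions <- tibble::as_tibble(fractions)
  n <- nrow(fractions)
  if (n < 1L) stop("nothing to pool", call. = FALSE)
  ord <- order(fractions$t_start)
  fractions <- fractions[ord, ]
  if (n > 1L &&
      any(abs(fractions$t_end[-n] - fractions$t_start[-1]) > 1e-9)) {
    stop("fractions to pool must be contiguous in time", call. = FALSE)
  }
  out <- fractions[1, ]
  out$t_start <- fractions$t_start[1]
  out$t_end <- fractions$t_end[n]
  if ("conc_uM" %in% names(fractions)) out$conc_uM <- mean(fractions$conc_uM)
  for (col in c("area_heavy", "area_light")) {
    if (col %in% names(fractions)) out[[col]] <- sum(fractions[[col]])
  }
  if ("n_pooled" %in% names(fractions)) {
    out$n_pooled <- sum(fractions$n_pooled)
  } else {
    out$n_pooled <- n
  }
  out
}

#' Express concentrations as percent of the pre-infusion baseline
#'
#' Each value is scaled by 100 over the mean of the baseline (pre-infusion)
#' fractions of the same subject, so every subject starts at 100%.
#'
#' @param conc Concentration series (uM).
#' @param is_baseline Logical vector marking baseline fractions (typically
#'   `t < 0`).
#' @return Percent-of-baseline series.
#' @examples
#' percent_of_baseline(c(30, 30, 23.13), c(TRUE, TRUE, FALSE))
#' @export
percent_of_baseline <- function(conc, is_baseline) {
  stopifnot(length(conc) == length(is_baseline))
  if (!any(is_baseline)) {
    stop("at least one baseline fraction is required", call. = FALSE)
  }
  base <- mean(conc[is_baseline])
  if (!is.finite(base) || base <= 0) {
    stop("baseline mean must be positive", call. = FALSE)
  }
  conc * 100 / base
}
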