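#' Packaged experimental-group presets for the synthetic cohort generator
#'
#' Three groups mirror the study design of the kainate rat model during a
#' 3-h [2,5-13C]glucose infusion: `I` controls (n = 6, no seizures), `II`
#' kainate-treated with infrequent seizures (n = 6, ~5 per 3 h) and `III`
#' kainate-treated with frequent seizures (n = 4, ~10 per 3 h). Group-level
#' parameters (C5 enrichment rates, baseline and endpoint concentrations,
#' seizure counts) are the published group summaries; between-subject SDs
#' are reconstructed from the printed standard errors as SE * sqrt(n).
#'
#' Concentration trajectories are piecewise linear: glutamate through
#' absolute-concentration knots (for group III: flat at baseline to 80 min,
#' gradual rise to 120 min, steeper rise to 5.51 uM at 167 min, then
#' constant), glutamine as percent of each subject's baseline declining to
#' the group endpoint at 170 min and constant after, so the final 5-min
#' fraction measures the endpoint. Group III glutamine enrichment carries a
#' positive offset chosen so the group mean is 0.23 at t = 67 min while the
#' fitted 0-110 min slope stays 0.00299/min (the free intercept of the rate
#' fit absorbs the offset).
#'
#' Measurement noise defaults (all multiplicative, mean-one lognormal):
#' enrichment CV 5%, concentration CV 10%, peak-area CV 2%.
#'
#' @return Named list (`I`, `II`, `III`) of `group_preset` lists.
#' @export
group_presets <- function() {
  noise <- list(enrichment_cv = 0.05, conc_cv = 0.10, area_cv = 0.02)
  presets <- list(
    I = list(
      label = "I", kainate = FALSE, n_subjects = 6L,
      glu_slope_mean = 0.00167, glu_slope_sd = 0.0001 * sqrt(6),
      gln_slope_mean = 0.00227, gln_slope_sd = 0.00008 * sqrt(6),
      gln_plateau_min = 110, gln_e_offset = 0,
      glu_baseline_mean = 1.27, glu_baseline_sd = 0.43 * sqrt(6),
      gln_baseline_mean = 29.9, gln_baseline_sd = 3.5 * sqrt(6),
      glu_knots = data.frame(t = c(0, 167), uM = c(1.27, 1.73)),
      gln_pct_knots = data.frame(t = c(0, 170), pct = c(100, 100)),
      seizure_mean = 0, noise = noise
    ),
    II = list(
      label = "II", kainate = TRUE, n_subjects = 6L,
      glu_slope_mean = 0.00172, glu_slope_sd = 0.0001 * sqrt(6),
      gln_slope_mean = 0.00265, gln_slope_sd = 0.0002 * sqrt(6),
      gln_plateau_min = 110, gln_e_offset = 0,
      glu_baseline_mean = 0.94, glu_baseline_sd = 0.069 * sqrt(6),
      gln_baseline_mean = 36.4, gln_baseline_sd = 3.0 * sqrt(6),
      glu_knots = data.frame(t = c(0, 167), uM = c(0.94, 1.04)),
      gln_pct_knots = data.frame(t = c(0, 170), pct = c(100, 77.1)),
      seizure_mean = 5, noise = noise
    ),
    III = list(
      label = "III", kainate = TRUE, n_subjects = 4L,
      glu_slope_mean = 0.0029, glu_slope_sd = 0.0001 * sqrt(4),
      gln_slope_mean = 0.00299, gln_slope_sd = 0.00027 * sqrt(4),
      gln_plateau_min = 110,
      # group mean C5 enrichment of 0.23 at the 67-min fraction
      gln_e_offset = 0.23 - 0.00299 * 67,
      glu_baseline_mean = 2.13, glu_baseline_sd = 1.0 * sqrt(4),
      gln_baseline_mean = 29.5, gln_baseline_sd = 2.7 * sqrt(4),
      glu_knots = data.frame(t = c(0, 80, 120, 125, 167),
                             uM = c(2.13, 2.13, 3.1, 3.3, 5.51)),
      gln_pct_knots = data.frame(t = c(0, 170), pct = c(100, 66.2)),
      seizure_mean = 10, noise = noise
    )
  )
  lapply(presets, validate_preset)
}

validate_preset <- function(preset) {
  stopifnot(preset$n_subjects >= 2L,
            preset$glu_slope_mean > 0, preset$gln_slope_mean > 0,
            preset$glu_slope_sd >= 0, preset$gln_slope_sd >= 0,
            preset$seizure_mean >= 0,
            !is.unsorted(preset$glu_knots$t, strictly = TRUE),
            !is.unsorted(preset$gln_pct_knots$t, strictly = TRUE))
  structure(preset, class = "group_preset")
}

#' Microdialysis fraction schedule of the infusion experiment
#'
#' Four 15-min baseline fractions before the infusion (t = -60 to 0), then
#' thirty-six 5-min fractions over the 3-h infusion (t = 0 to 180), all in
#' minutes relative to infusion start.
#'
#' @return Tibble: `fraction`, `t_start`, `t_end`, `phase`.
#' @export
fraction_schedule <- function() {
  starts <- c(seq(-60, -15, by = 15), seq(0, 175, by = 5))
  widths <- c(rep(15, 4), rep(5, 36))
  tibble::tibble(
    fraction = seq_along(starts),
    t_start = starts,
    t_end = starts + widths,
    phase = rep(c("baseline", "infusion"), c(4, 36))
  )
}

#' GC-MS pooling plan over the fraction schedule
#'
#' Single 5-min dialysate fractions carry too little analyte for SIM, so
#' 2-3 consecutive infusion fractions are pooled before derivatization.
#' The packaged plan alternates pools of 3 and 2 fractions (ending with two
#' pools of 3), which places pooled reported times at 4.5, 17, 29.5, 42,
#' 54.5, 67, ... minutes; baseline 15-min fractions are analyzed singly.
#'
#' @return The [fraction_schedule()] tibble with a `pool` column.
#' @export
gcms_pooling_plan <- function() {
  sched <- fraction_schedule()
  sizes <- c(rep(c(3, 2), 6), 3, 3)
  stopifnot(sum(sizes) == 36)
  pool_inf <- rep(seq_along(sizes), sizes)
  sched$pool <- c(paste0("B", 1:4), paste0("P", pool_inf))
  sched
}
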