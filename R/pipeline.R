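#' Default run configuration
#'
#' Bundles everything the analysis pipeline needs: the heavy-isotope
#' abundance table, ion-pair definitions, label-scrambling models, the
#' per-analyte rate-fit windows (glutamate 0-120 min; glutamine 0-110 min,
#' after which its enrichment levels off), the probe dead time (180 s),
#' the frequent-seizure classification cutoff (8 per 3 h) and the
#' significance levels. Every entry can be overridden.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `"ecflux_config"`.
#' @examples
#' cfg <- default_config(dead_time_s = 0)
#' @export
default_config <- function(...) {
  config <- list(
    abundance = default_abundance_table(),
    ion_pairs = default_ion_pairs(),
    scrambling = scrambling_presets(),
    fit_windows = list(GLU = c(0, 120), GLN = c(0, 110)),
    dead_time_s = 180,
    seizure_cutoff = 8,
    alphas = c(0.05, 0.01),
    concordance_tol = 0.01,
    sim_area_scale = 1e5
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  structure(config, class = "ecflux_config")
}

#' C5 enrichment time series from SIM peak areas
#'
#' The measurement-to-enrichment stage of the pipeline: member fractions
#' are pooled (areas summed over each subject/analyte/pool/ion pair), each
#' ion pair's heavy/light ratio is converted to aggregate C2-C5 fractional
#' enrichment with its natural-abundance correction factor, the designated
#' C2-C5 pairs are averaged (flagging pools whose pairs disagree by more
#' than the concordance tolerance), and the time-dependent scrambling
#' correction isolates the C5 positional enrichment at the dead-time
#' corrected pooled midpoint.
#'
#' @param areas Long-format area table: `subject`, `analyte`, `t_start`,
#'   `t_end`, `pool`, `pair`, `area_heavy`, `area_light` (as written by
#'   [simulate_cohort()]).
#' @param config See [default_config()].
#' @return Tibble: `subject`, `analyte`, `t_min`, `e_c2c5`, `e_c5`,
#'   `below_baseline`, `discordant`, `extrapolated` (scrambling model used
#'   beyond 180 min).
#' @export
compute_enrichment_series <- function(areas, config = default_config()) {
  required <- c("subject", "analyte", "t_start", "t_end", "pool", "pair",
                "area_heavy", "area_light")
  missing <- setdiff(required, names(areas))
  if (length(missing)) {
    stop("area table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- config$ion_pairs
  pooled <- areas |>
    dplyr::group_by(.data$subject, .data$analyte, .data$pool, .data$pair) |>
    dplyr::summarise(t_start = min(.data$t_start), t_end = max(.data$t_end),
                     area_heavy = sum(.data$area_heavy),
                     area_light = sum(.data$area_light), .groups = "drop") |>
    dplyr::inner_join(
      pairs[c("analyte", "pair", "carbons", "correction_factor",
              "use_for_mean")],
      by = c("analyte", "pair"))
  unmatched <- dplyr::anti_join(
    dplyr::distinct(areas[c("analyte", "pair")]),
    pairs[c("analyte", "pair")], by = c("analyte", "pair"))
  if (nrow(unmatched)) {
    stop("no ion-pair definition for: ",
         paste(unmatched$analyte, unmatched$pair, collapse = ", "),
         call. = FALSE)
  }
  pooled$e_pair <- fractional_enrichment(pooled$area_heavy,
                                         pooled$area_light,
                                         pooled$correction_factor)
  series <- pooled |>
    dplyr::filter(.data$use_for_mean) |>
    dplyr::group_by(.data$subject, .data$analyte, .data$pool) |>
    dplyr::summarise(
      t_start = .data$t_start[1], t_end = .data$t_end[1],
      e_c2c5 = mean(.data$e_pair),
      discordant = (max(.data$e_pair) - min(.data$e_pair)) >
        config$concordance_tol,
      .groups = "drop")
  series$t_min <- reported_time(series$t_start, series$t_end,
                                config$dead_time_s)
  series$below_baseline <- series$e_c2c5 < 0
  series <- series |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(df, key) {
      model <- config$scrambling[[key$analyte]]
      if (is.null(model)) {
        stop("no scrambling model for analyte ", key$analyte, call. = FALSE)
      }
      df$e_c5 <- c5_enrichment(df$e_c2c5, df$t_min, model)
      df
    }) |>
    dplyr::ungroup()
  series$extrapolated <- series$t_min > 180
  series |>
    dplyr::select("subject", "analyte", "t_min", "e_c2c5", "e_c5",
                  "below_baseline", "discordant", "extrapolated") |>
    dplyr::arrange(.data$subject, .data$analyte, .data$t_min)
}

#' Per-subject enrichment rates over the configured fit windows
#'
#' Applies [fit_rate()] to each subject/analyte series using that analyte's
#' fit window from the configuration.
#'
#' @param series Enrichment series from [compute_enrichment_series()].
#' @param config See [default_config()].
#' @return Tibble: `subject`, `analyte`, `slope`, `intercept`, `se_slope`,
#'   `sigma`, `n`, `t0`, `t1`.
#' @export
fit_rates_table <- function(series, config = default_config()) {
  series |>
    dplyr::group_by(.data$subject, .data$analyte) |>
    dplyr::group_modify(function(df, key) {
      window <- config$fit_windows[[key$analyte]]
      if (is.null(window)) {
        stop("no fit window for analyte ", key$analyte, call. = FALSE)
      }
      fit_rate(df$t_min, df$e_c5, window = window)
    }) |>
    dplyr::ungroup()
}

#' Concentration series as percent of pre-infusion baseline
#'
#' Converts each subject/analyte HPLC concentration series to percent of
#' its own pre-infusion baseline (fractions with negative reported time).
#'
#' @param fractions HPLC table: `subject`, `analyte`, `t_start`, `t_end`,
#'   `conc_uM`.
#' @param config See [default_config()].
#' @return Tibble: `subject`, `analyte`, `t_min`, `conc_uM`, `pct_baseline`.
#' @export
concentration_pct <- function(fractions, config = default_config()) {
  fractions |>
    dplyr::mutate(t_min = reported_time(.data$t_start, .data$t_end,
                                        config$dead_time_s)) |>
    dplyr::group_by(.data$subject, .data$analyte) |>
    dplyr::mutate(pct_baseline = percent_of_baseline(.data$conc_uM,
                                                     .data$t_min < 0)) |>
    dplyr::ungroup() |>
    dplyr::select("subject", "analyte", "t_min", "conc_uM", "pct_baseline") |>
    dplyr::arrange(.data$subject, .data$analyte, .data$t_min)
}

#' Run the full analysis pipeline on a cohort
#'
#' End-to-end orchestration on a measured (or simulated) cohort: classify
#' subjects from their seizure counts, convert SIM areas to C5 enrichment
#' series, fit per-subject enrichment rates, summarize rates per group,
#' normalize concentrations to baseline, and run the statistical layer
#' (one-way ANOVA plus Scheffe and Tukey-Kramer post-hocs) on the rates and
#' the final-fraction concentration endpoints. Deterministic given its
#' inputs.
#'
#' @param cohort List with `subjects` (columns `subject`, `kainate`,
#'   `seizure_count`), `fractions` and `areas`, as from [simulate_cohort()]
#'   or [read_cohort()].
#' @param config See [default_config()].
#' @return List of class `"ecflux_result"`: `series`, `rates` (with group
#'   labels), `group_rates`, `conc_pct`, `endpoints`, `stats` (per-endpoint
#'   ANOVA + post-hoc tables), `manifest`.
#' @export
run_pipeline <- function(cohort, config = default_config()) {
  subj <- cohort$subjects
  subj$group <- classify_subject(subj$seizure_count, subj$kainate,
                                 config$seizure_cutoff)
  series <- compute_enrichment_series(cohort$areas, config)
  rates <- fit_rates_table(series, config) |>
    dplyr::inner_join(subj[c("subject", "group")], by = "subject")
  grp_rates <- rates |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ group_rates(.x)) |>
    dplyr::ungroup()
  conc <- concentration_pct(cohort$fractions, config) |>
    dplyr::inner_join(subj[c("subject", "group")], by = "subject")
  endpoints <- conc |>
    dplyr::group_by(.data$subject, .data$analyte, .data$group) |>
    dplyr::slice_max(.data$t_min, n = 1) |>
    dplyr::ungroup()

  stats_tables <- list()
  for (a in unique(rates$analyte)) {
    r <- rates[rates$analyte == a, ]
    if (length(unique(r$group)) >= 2L && all(table(r$group) >= 2L)) {
      stats_tables[[paste0("rate_", a)]] <- endpoint_stats(
        r$slope, r$group, config$alphas)
    }
    e <- endpoints[endpoints$analyte == a, ]
    val <- if (a == "GLN") e$pct_baseline else e$conc_uM
    if (length(unique(e$group)) >= 2L && all(table(e$group) >= 2L)) {
      stats_tables[[paste0("endpoint_", a)]] <- endpoint_stats(
        val, e$group, config$alphas)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecflux")),
    dead_time_s = config$dead_time_s,
    fit_windows = config$fit_windows,
    seizure_cutoff = config$seizure_cutoff,
    concordance_tol = config$concordance_tol,
    n_subjects = nrow(subj),
    n_discordant_pools = sum(series$discordant),
    n_extrapolated = sum(series$extrapolated)
  )
  structure(list(series = series, rates = rates, group_rates = grp_rates,
                 conc_pct = conc, endpoints = endpoints,
                 stats = stats_tables, manifest = manifest),
            class = "ecflux_result")
}

endpoint_stats <- function(values, groups, alphas = c(0.05, 0.01)) {
  aov1 <- one_way_anova(values, groups)
  list(anova = aov1,
       posthoc = dplyr::bind_rows(scheffe(values, groups, alphas),
                                  tukey_kramer(values, groups, alphas)))
}

#' @export
print.ecflux_result <- function(x, ...) {
  cat("ecflux pipeline result:", x$manifest$n_subjects, "subjects\n")
  cat("Group enrichment rates (fractional enrichment/min):\n")
  print(as.data.frame(x$group_rates), digits = 3)
  invisible(x)
}

#' Write pipeline outputs as tidy CSV plus a JSON manifest
#'
#' Emits `enrichment_series.csv`, `rates.csv`, `group_rates.csv`,
#' `concentrations.csv`, `endpoints.csv`, `stats.csv` (per-endpoint ANOVA F,
#' dfs, p and post-hoc significance flags) and `manifest.json`.
#'
#' @param result An `"ecflux_result"` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$series, file.path(dir, "enrichment_series.csv"))
  readr::write_csv(result$rates, file.path(dir, "rates.csv"))
  readr::write_csv(result$group_rates, file.path(dir, "group_rates.csv"))
  readr::write_csv(result$conc_pct, file.path(dir, "concentrations.csv"))
  readr::write_csv(result$endpoints, file.path(dir, "endpoints.csv"))
  stats_rows <- lapply(names(result$stats), function(nm) {
    s <- result$stats[[nm]]
    ph <- s$posthoc
    ph$endpoint <- nm
    ph$f_anova <- s$anova$f
    ph$df_between <- s$anova$df_between
    ph$df_within <- s$anova$df_within
    ph$p_anova <- s$anova$p
    ph
  })
  if (length(stats_rows)) {
    readr::write_csv(dplyr::bind_rows(stats_rows), file.path(dir, "stats.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
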