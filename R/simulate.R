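# Forward model of one study subject: true per-subject parameters ->
# seizure events, HPLC concentration fractions and SIM peak areas.

draw_positive_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Poisson count conditioned to lie within +/- 3 of its mean
draw_seizure_count <- function(mean) {
  if (mean <= 0) return(0L)
  repeat {
    x <- stats::rpois(1, mean)
    if (abs(x - mean) <= 3) return(as.integer(x))
  }
}

# true C5 enrichment at reported time t (vectorized over t)
true_c5 <- function(t, slope, offset = 0, plateau = Inf) {
  ifelse(t <= 0, 0, offset + slope * pmin(t, plateau))
}

# subject's true concentration (uM) at reported time t
true_conc <- function(t, analyte, preset, baseline) {
  if (analyte == "GLU") {
    knots <- preset$glu_knots
    scale <- baseline / knots$uM[1]
    vals <- stats::approx(knots$t, knots$uM * scale, xout = pmax(t, 0),
                          rule = 2)$y
  } else {
    knots <- preset$gln_pct_knots
    pct <- stats::approx(knots$t, knots$pct, xout = pmax(t, 0), rule = 2)$y
    vals <- baseline * pct / 100
  }
  vals
}

#' Simulate one subject of a synthetic cohort
#'
#' Draws subject-level truth from a [group_presets()] entry (enrichment
#' slopes, baseline concentrations, seizure count) and forward-models the
#' complete measurement record: seizure events, per-fraction HPLC
#' concentrations, and SIM peak areas for every configured ion pair on the
#' GC-MS pooling plan. The C5 enrichment truth is linear in reported time
#' (glutamine plateaus at 110 min); the aggregate C2-C5 truth is the C5
#' truth inflated by 1/(1 - rho(t)) so that the positional correction of
#' the analysis pipeline inverts it exactly. Peak areas within a pool are
#' generated from the pooled-center truth, so pooling loses no information.
#' Randomness comes from the caller's RNG state (`set.seed()`).
#'
#' @param preset A `group_preset` from [group_presets()].
#' @param subject_id Subject identifier string.
#' @param config Pipeline configuration, see [default_config()].
#' @return List with tibbles `subject` (one row of truth + observables),
#'   `events`, `fractions` (HPLC), `areas` (member-fraction SIM areas with
#'   a `pool` column).
#' @export
simulate_subject <- function(preset, subject_id = "S1",
                             config = default_config()) {
  stopifnot(inherits(preset, "group_preset"))
  noise <- preset$noise
  slopes <- c(
    GLU = draw_positive_normal(1, preset$glu_slope_mean, preset$glu_slope_sd),
    GLN = draw_positive_normal(1, preset$gln_slope_mean, preset$gln_slope_sd)
  )
  baselines <- c(
    GLU = preset$glu_baseline_mean *
      rlnorm_cv(1, preset$glu_baseline_sd / preset$glu_baseline_mean),
    GLN = preset$gln_baseline_mean *
      rlnorm_cv(1, preset$gln_baseline_sd / preset$gln_baseline_mean)
  )
  offsets <- c(GLU = 0, GLN = preset$gln_e_offset)
  plateaus <- c(GLU = Inf, GLN = preset$gln_plateau_min)

  n_seiz <- draw_seizure_count(preset$seizure_mean)
  events <- tibble::tibble(
    subject = subject_id,
    onset_min = sort(stats::runif(n_seiz, 0, 180)),
    duration_s = stats::runif(n_seiz, 15, 90),
    onset_type = sample(c("hypersynchronous", "low-voltage-fast"),
                        n_seiz, replace = TRUE, prob = c(0.74, 0.26))
  )

  sched <- gcms_pooling_plan()
  rt_frac <- reported_time(sched$t_start, sched$t_end, config$dead_time_s)
  pools <- sched |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(p_start = min(.data$t_start), p_end = max(.data$t_end),
                     .groups = "drop")
  rt_pool <- reported_time(pools$p_start, pools$p_end, config$dead_time_s)

  fractions <- list()
  areas <- list()
  for (analyte in c("GLU", "GLN")) {
    conc_truth <- true_conc(rt_frac, analyte, preset, baselines[[analyte]])
    fractions[[analyte]] <- tibble::tibble(
      subject = subject_id, analyte = analyte,
      t_start = sched$t_start, t_end = sched$t_end,
      conc_uM = conc_truth * rlnorm_cv(nrow(sched), noise$conc_cv)
    )

    model <- config$scrambling[[analyte]]
    e_c5 <- true_c5(rt_pool, slopes[[analyte]], offsets[[analyte]],
                    plateaus[[analyte]])
    e_agg <- aggregate_from_c5(e_c5, rt_pool, model)
    e_noisy <- pmin(e_agg * rlnorm_cv(length(e_agg), noise$enrichment_cv),
                    0.95)
    pool_e <- stats::setNames(e_noisy, pools$pool)

    pairs <- config$ion_pairs[config$ion_pairs$analyte == analyte, ]
    grid <- tidyr::expand_grid(
      sched[c("t_start", "t_end", "pool")],
      pair = pairs$pair
    )
    grid$correction <- pairs$correction_factor[match(grid$pair, pairs$pair)]
    members <- stats::setNames(tabulate(factor(sched$pool)),
                               levels(factor(sched$pool)))
    grid$e_pool <- pool_e[grid$pool]
    base_area <- config$sim_area_scale / members[grid$pool]
    ratio <- grid$correction + grid$e_pool / (1 - grid$e_pool)
    n <- nrow(grid)
    areas[[analyte]] <- tibble::tibble(
      subject = subject_id, analyte = analyte,
      t_start = grid$t_start, t_end = grid$t_end, pool = grid$pool,
      pair = grid$pair,
      area_heavy = as.numeric(base_area * ratio * rlnorm_cv(n, noise$area_cv)),
      area_light = as.numeric(base_area * rlnorm_cv(n, noise$area_cv))
    )
  }

  subject <- tibble::tibble(
    subject = subject_id, group = preset$label, kainate = preset$kainate,
    seizure_count = n_seiz,
    glu_slope_true = slopes[["GLU"]], gln_slope_true = slopes[["GLN"]],
    glu_baseline_true = baselines[["GLU"]],
    gln_baseline_true = baselines[["GLN"]],
    gln_offset_true = preset$gln_e_offset
  )
  list(subject = subject, events = events,
       fractions = dplyr::bind_rows(fractions),
       areas = dplyr::bind_rows(areas))
}

#' Simulate a complete synthetic cohort
#'
#' Generates every subject of the given group presets (by default the three
#' packaged study groups: 6 controls, 6 infrequently seizing, 4 frequently
#' seizing), reproducibly under a master seed, and optionally writes the
#' cohort tables as CSV. The `subjects` table carries the per-subject truth
#' (true slopes, baselines) used only for recovery scoring, kept separate
#' from the measurement tables consumed by the analysis pipeline.
#'
#' @param presets List of `group_preset`s (default [group_presets()]).
#' @param seed Master seed (integer) or `NULL` to use the current RNG state.
#' @param config Pipeline configuration, see [default_config()].
#' @param dir Optional directory: writes `subjects.csv` (truth),
#'   `events.csv`, `fractions.csv` and `areas.csv`.
#' @return List of tibbles: `subjects`, `events`, `fractions`, `areas`.
#' @examples
#' cohort <- simulate_cohort(group_presets()["III"], seed = 1)
#' @export
simulate_cohort <- function(presets = group_presets(), seed = NULL,
                            config = default_config(), dir = NULL) {
  stopifnot(length(presets) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  parts <- list()
  i <- 0L
  for (preset in presets) {
    for (k in seq_len(preset$n_subjects)) {
      i <- i + 1L
      parts[[i]] <- simulate_subject(
        preset, sprintf("%s-%02d", preset$label, k), config)
    }
  }
  cohort <- list(
    subjects = dplyr::bind_rows(lapply(parts, `[[`, "subject")),
    events = dplyr::bind_rows(lapply(parts, `[[`, "events")),
    fractions = dplyr::bind_rows(lapply(parts, `[[`, "fractions")),
    areas = dplyr::bind_rows(lapply(parts, `[[`, "areas"))
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write / read a synthetic cohort as CSV
#'
#' `write_cohort()` writes `subjects.csv` (per-subject truth), `events.csv`,
#' `fractions.csv` (HPLC concentrations) and `areas.csv` (SIM peak areas,
#' long format: one row per member fraction and ion pair). `read_cohort()`
#' reads them back into the same list structure.
#'
#' @param cohort List as returned by [simulate_cohort()].
#' @param dir Directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("subjects", "events", "fractions", "areas")) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- lapply(c(subjects = "subjects", events = "events",
                  fractions = "fractions", areas = "areas"),
                function(nm) readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                                             show_col_types = FALSE))
  out
}
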