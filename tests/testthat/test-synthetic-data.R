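test_that("the fraction schedule and pooling plan match the study design", {
  sched <- fraction_schedule()
  expect_equal(nrow(sched), 40L)
  expect_equal(sum(sched$phase == "baseline"), 4L)
  expect_equal(unique(sched$t_end - sched$t_start), c(15, 5))
  expect_equal(min(sched$t_start), -60)
  expect_equal(max(sched$t_end), 180)
  plan <- gcms_pooling_plan()
  sizes <- table(plan$pool[plan$phase == "infusion"])
  expect_true(all(sizes %in% 2:3))
  # a pooled fraction reports exactly at the 67-min comparison point
  pools <- aggregate(cbind(t_start, t_end) ~ pool, plan,
                     function(x) range(x)[c(1, 2)])
  rt <- reported_time(pools$t_start[, 1], pools$t_end[, 2])
  expect_true(any(abs(rt - 67) < 1e-9))
})

test_that("a noiseless cohort closes the pipeline exactly", {
  p3 <- noiseless_preset(group_presets()$III)
  cohort <- simulate_cohort(list(p3), seed = 1)
  series <- compute_enrichment_series(cohort$areas)
  rates <- suppressWarnings(fit_rates_table(series))
  expect_equal(rates$slope[rates$analyte == "GLU"], rep(0.0029, 4))
  expect_equal(rates$slope[rates$analyte == "GLN"], rep(0.00299, 4))
  # the glutamine offset lands in the intercept, not the slope
  expect_equal(rates$intercept[rates$analyte == "GLN"],
               rep(0.23 - 0.00299 * 67, 4))
  # enrichment at the 67-min fraction equals the preset anchor
  at67 <- series[series$analyte == "GLN" & abs(series$t_min - 67) < 1e-9, ]
  expect_equal(at67$e_c5, rep(0.23, 4))
  # concentration endpoints equal the preset values exactly
  conc <- concentration_pct(cohort$fractions)
  last <- conc[conc$t_min == max(conc$t_min), ]
  expect_equal(last$pct_baseline[last$analyte == "GLN"], rep(66.2, 4))
  expect_equal(last$conc_uM[last$analyte == "GLU"], rep(5.51, 4))
  # pre-infusion pools carry zero enrichment
  expect_true(all(series$e_c5[series$t_min < 0] == 0))
})

test_that("cohort simulation is reproducible and seed-sensitive", {
  presets <- group_presets()["III"]
  a <- simulate_cohort(presets, seed = 42)
  b <- simulate_cohort(presets, seed = 42)
  expect_identical(a, b)
  c <- simulate_cohort(presets, seed = 43)
  expect_false(identical(a$areas$area_heavy, c$areas$area_heavy))
  # same truth structure: identical shapes and schedules
  expect_identical(dim(a$areas), dim(c$areas))
  expect_identical(a$fractions[c("t_start", "t_end")],
                   c$fractions[c("t_start", "t_end")])
})

test_that("cohorts carry the designed group structure", {
  cohort <- simulate_cohort(group_presets(), seed = 7)
  expect_equal(nrow(cohort$subjects), 16L)
  expect_equal(as.integer(table(cohort$subjects$group)[c("I", "II", "III")]),
               c(6L, 6L, 4L))
  # controls never seize
  ctrl <- cohort$subjects$subject[cohort$subjects$group == "I"]
  expect_equal(sum(cohort$events$subject %in% ctrl), 0L)
  expect_true(all(cohort$subjects$seizure_count[
    cohort$subjects$group == "I"] == 0))
  # event durations within the generated range, onsets inside the infusion
  expect_true(all(cohort$events$duration_s >= 15 &
                    cohort$events$duration_s <= 90))
  expect_true(all(cohort$events$onset_min >= 0 &
                    cohort$events$onset_min <= 180))
  expect_true(all(cohort$events$onset_type %in%
                    c("hypersynchronous", "low-voltage-fast")))
})

test_that("seizure counts concentrate near the preset means", {
  set.seed(31)
  counts <- replicate(500, ecflux:::draw_seizure_count(5))
  k <- 2:8
  mean_cond <- sum(k * dpois(k, 5)) / sum(dpois(k, 5))
  expect_lt(abs(mean(counts) - mean_cond), 2 * sd(counts) / sqrt(500))
  expect_true(all(abs(counts - 5) <= 3))
})

test_that("analysis results do not depend on the truth columns", {
  cohort <- simulate_cohort(group_presets()["II"], seed = 3)
  blinded <- cohort
  blinded$subjects <- blinded$subjects[c("subject", "kainate",
                                         "seizure_count")]
  res_full <- run_pipeline(cohort)
  res_blind <- run_pipeline(blinded)
  expect_equal(res_blind$rates, res_full$rates)
  expect_equal(res_blind$group_rates, res_full$group_rates)
  expect_equal(res_blind$endpoints$pct_baseline,
               res_full$endpoints$pct_baseline)
})
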