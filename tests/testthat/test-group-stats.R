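test_that("one-way ANOVA matches hand sums and stats::aov", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_anova(vals, grp)
  # hand decomposition: SSB = 6, MSB = 3, SSW = 6, MSW = 1
  expect_equal(res$f, 3)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 6L)
  expect_equal(res$msw, 1)
  # identical groups
  expect_equal(one_way_anova(rep(1:3, 2), rep(c("a", "b"), each = 3))$f, 0)
  # zero within-variance with distinct means: degenerate infinite F
  deg <- one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_true(is.infinite(deg$f) && deg$degenerate)
  expect_equal(deg$p, 0)
  # independent oracle: stats::aov on random unequal-n data
  set.seed(12)
  vals <- rnorm(16, mean = rep(c(0, 0.5, 1), c(6, 6, 4)))
  grp <- rep(c("a", "b", "c"), c(6, 6, 4))
  res <- one_way_anova(vals, grp)
  ref <- summary(stats::aov(vals ~ grp))[[1]]
  expect_equal(res$f, ref[["F value"]][1], tolerance = 1e-12)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-12)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("summary-based ANOVA is consistent with the raw-data ANOVA", {
  set.seed(13)
  vals <- rnorm(16, mean = rep(c(0, 1, 3), c(6, 6, 4)))
  grp <- rep(c("a", "b", "c"), c(6, 6, 4))
  raw <- one_way_anova(vals, grp)
  means <- tapply(vals, grp, mean)
  ses <- tapply(vals, grp, sd) / sqrt(c(6, 6, 4))
  from_sum <- anova_from_summary(means, ses, c(6, 6, 4))
  expect_equal(from_sum$f, raw$f, tolerance = 1e-12)
  expect_equal(from_sum$p, raw$p, tolerance = 1e-12)
  # equal means give F = 0; a duplicated group gives F = 0
  expect_equal(anova_from_summary(c(1, 1), c(0.1, 0.1), c(5, 5))$f, 0)
  expect_error(anova_from_summary(c(1, 2), c(0.1, 0), c(5, 5)), "positive")
})

test_that("rate-table group summaries give a large but rounded-inflated F", {
  # reconstructing the 3-group comparison of enrichment rates from printed
  # group summaries (0.00167/0.00172/0.0029, SE 0.0001, n = 6, 6, 4):
  # hand sum-of-squares oracle; rounding of the summaries inflates F well
  # above the value computed from raw data
  means <- c(0.00167, 0.00172, 0.0029)
  ses <- c(0.0001, 0.0001, 0.0001)
  ns <- c(6, 6, 4)
  res <- anova_from_summary(means, ses, ns)
  sds <- ses * sqrt(ns)
  grand <- sum(ns * means) / sum(ns)
  f_oracle <- (sum(ns * (means - grand)^2) / 2) /
    (sum((ns - 1) * sds^2) / (sum(ns) - 3))
  expect_equal(res$f, f_oracle, tolerance = 1e-12)
  expect_gt(res$f, 30) # ~39 from rounded summaries
  expect_lt(res$p, 0.01)
})

test_that("Tukey-Kramer agrees with stats::TukeyHSD on unequal groups", {
  set.seed(14)
  vals <- rnorm(16, mean = rep(c(0, 0.3, 1.2), c(6, 6, 4)))
  grp <- rep(c("a", "b", "c"), c(6, 6, 4))
  ours <- tukey_kramer(vals, grp)
  ref <- stats::TukeyHSD(stats::aov(vals ~ factor(grp)))$`factor(grp)`
  # TukeyHSD labels pairs "b-a", "c-a", "c-b" with diff = later - earlier
  key <- paste0(ours$group2, "-", ours$group1)
  expect_equal(unname(-ours$diff), unname(ref[key, "diff"]),
               tolerance = 1e-9)
  expect_equal(unname(ours$p), unname(ref[key, "p adj"]), tolerance = 1e-9)
})

test_that("post-hoc flags are nested and detect a well-separated group", {
  set.seed(15)
  # one group shifted by 5 within-group SDs: both tests call it at 0.01
  vals <- c(rnorm(6, 0), rnorm(6, 0.2), rnorm(4, 5))
  grp <- rep(c("a", "b", "c"), c(6, 6, 4))
  for (fun in list(scheffe, tukey_kramer)) {
    res <- fun(vals, grp)
    expect_true(all(res$sig_0.05[res$sig_0.01])) # 0.01 implies 0.05
    expect_true(res$sig_0.01[res$group1 == "a" & res$group2 == "c"])
  }
  # identical groups are never significant
  same <- rep(c(0.1, 0.2, 0.3), 2)
  g2 <- rep(c("a", "b"), each = 3)
  expect_false(any(scheffe(same, g2)$sig_0.05))
  expect_false(any(tukey_kramer(same, g2)$sig_0.05))
})

test_that("Scheffe is more conservative than Tukey pairwise", {
  set.seed(16)
  for (i in 1:10) {
    vals <- rnorm(16, mean = rep(c(0, 0.5, 1), c(6, 6, 4)))
    grp <- rep(c("a", "b", "c"), c(6, 6, 4))
    s <- scheffe(vals, grp)
    tk <- tukey_kramer(vals, grp)
    expect_true(all(s$p >= tk$p - 1e-9))
  }
})
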