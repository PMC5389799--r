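test_that("composition strings parse into atom counts", {
  expect_equal(parse_composition("C16H21N1O2Si2"),
               c(C = 16L, H = 21L, N = 1L, O = 2L, Si = 2L))
  expect_equal(parse_composition("CH4"), c(C = 1L, H = 4L))
  expect_equal(parse_composition("C2C3"), c(C = 5L)) # repeated symbols add
  expect_error(parse_composition(""), "empty")
  expect_error(parse_composition("C16x2"), "cannot parse")
})

test_that("linear M+1 factor reproduces the published fragment factors", {
  # m/z 330 glutamate fragment: 27.8% at reported precision
  expect_equal(100 * mplus1_fraction("C16H21N1O2Si2"), 27.8,
               tolerance = 0.3 / 27.8)
  # single carbon atom
  expect_equal(mplus1_fraction(c(C = 1L)), 0.011)
  # m/z 272 fragment: hand sum 12*0.011 + 26*0.00015 + 0.0037 + 2*0.0004
  # + 2*0.047 = 0.2344, the 273/272 factor
  expect_equal(mplus1_fraction("C12H26N1O2Si2"), 0.2344, tolerance = 1e-12)
  expect_error(mplus1_fraction(c(C = 1L, Xx = 2L)), "Xx")
})

test_that("packaged correction factors are recomputable from compositions", {
  pairs <- default_ion_pairs()
  derived <- vapply(pairs$composition, mplus1_fraction, numeric(1))
  expect_true(all(abs(derived - pairs$correction_factor) <= 0.01))
  expect_equal(pairs$heavy_mz, pairs$light_mz + 1L)
})

test_that("linear factor is additive and exact factor dominates it", {
  set.seed(42)
  for (i in 1:25) {
    x <- c(C = sample(1:30, 1), H = sample(0:60, 1), N = sample(0:3, 1),
           O = sample(0:6, 1), Si = sample(0:3, 1))
    y <- c(C = sample(1:30, 1), H = sample(0:60, 1))
    xy <- x
    xy[names(y)] <- xy[names(y)] + y
    # additivity over composition concatenation
    expect_equal(mplus1_fraction(xy),
                 mplus1_fraction(x) + mplus1_fraction(y), tolerance = 1e-12)
    # exact >= linear; close when no silicon (all abundances < 0.05)
    lin <- mplus1_fraction(x)
    exact <- mplus1_fraction(x, method = "exact")
    expect_gte(exact, lin)
    if (x[["Si"]] == 0) expect_lt((exact - lin) / lin, 0.01)
  }
})

test_that("fractional enrichment formula and its edge cases", {
  # A/B equal to the correction factor: unenriched
  expect_equal(fractional_enrichment(27.8, 100, 0.278), 0)
  # A/B - C = 1 gives E = 0.5
  expect_equal(fractional_enrichment(127.8, 100, 0.278), 0.5)
  # below natural abundance: negative, retained
  expect_lt(fractional_enrichment(20, 100, 0.278), 0)
  expect_error(fractional_enrichment(10, 0, 0.278), "positive")
  expect_error(fractional_enrichment(10, 100, 1.2), "correction")
  expect_error(fractional_enrichment(0, 100, 0.99999),
               NA) # C < 1 with A = 0 stays above the degenerate pole
  expect_error(fractional_enrichment(0, 1, 2), "correction")
})

test_that("forward model inverts exactly and is monotone", {
  # noiseless round trip over an enrichment/correction grid
  for (C in c(0.161, 0.234, 0.278, 0.362, 0.9)) {
    E <- seq(0, 0.95, by = 0.05)
    ab <- simulate_peak_areas(E, C, area_light = 1234)
    expect_equal(fractional_enrichment(ab$area_heavy, ab$area_light, C), E,
                 tolerance = 1e-12)
  }
  # hand-evaluated forward examples
  expect_equal(simulate_peak_areas(0, 0.278, area_light = 1000)$area_heavy,
               278)
  expect_equal(simulate_peak_areas(0.5, 0.278, area_light = 100)$area_heavy,
               127.8)
  expect_equal(simulate_peak_areas(0.2, 0.161, area_light = 400)$area_heavy,
               400 * (0.161 + 0.25))
  # strictly increasing in A/B; zero iff A/B == C
  e <- fractional_enrichment(sort(c(seq(10, 130, 10), 27.8)), 100, 0.278)
  expect_true(all(diff(e) > 0))
  expect_equal(sum(e == 0), 1L)
  expect_error(simulate_peak_areas(1, 0.278), "< 1")
})

test_that("peak-area noise is reproducible and mean-preserving", {
  set.seed(7)
  a <- simulate_peak_areas(0.3, 0.278, cv = 0.05)
  set.seed(7)
  b <- simulate_peak_areas(0.3, 0.278, cv = 0.05)
  expect_identical(a, b)
  set.seed(8)
  many <- simulate_peak_areas(rep(0.3, 20000), 0.278, cv = 0.05)
  expect_equal(mean(many$area_light), 1e5, tolerance = 0.002)
})

test_that("ion-pair averaging applies the 1% concordance rule", {
  r <- mean_ion_pair_enrichment(c(0.200, 0.204))
  expect_equal(r$enrichment, 0.202)
  expect_false(r$discordant)
  r <- mean_ion_pair_enrichment(c(0.20, 0.23))
  expect_equal(r$enrichment, 0.215)
  expect_true(r$discordant)
  r <- mean_ion_pair_enrichment(0.17)
  expect_equal(r$enrichment, 0.17)
  expect_false(r$discordant)
  expect_error(mean_ion_pair_enrichment(numeric(0)), "at least one")
  expect_error(mean_ion_pair_enrichment(c(0.2, 0.21), c("C2-C5", "C1-C5")),
               "carbon spans")
})

test_that("ion-pair CSVs read back with derived factors when needed", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(
    analyte = c("GLU", "GLU"), light_mz = c(330L, 272L),
    heavy_mz = c(331L, 273L), carbons = "C2-C5",
    composition = c("C16H21N1O2Si2", "C12H26N1O2Si2"),
    correction_factor = c(0.278, NA)), path)
  pairs <- read_ion_pairs(path)
  # explicit factor wins; missing factor derived from composition
  expect_equal(pairs$correction_factor, c(0.278, 0.2344), tolerance = 1e-9)
  expect_true(all(pairs$use_for_mean))
})
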