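test_that("availability categories are exhaustive and follow the sparsity rule", {
  n <- 200
  all_na <- make_weekly(rep(NA_real_, n))
  expect_identical(categorize_series(all_na), "no_data")

  full <- make_weekly(runif(n, 0, 100))
  expect_identical(categorize_series(full), "complete")

  spikes <- rep(NA_real_, n)
  spikes[c(10, 50, 90, 130, 170)] <- 100
  expect_identical(categorize_series(make_weekly(spikes)), "peaks_only")

  some <- runif(n, 0, 100)
  some[c(20:24, 80:86)] <- NA
  expect_identical(categorize_series(make_weekly(some)), "incomplete")
})

test_that("margin cropping removes only leading/trailing gaps and is idempotent", {
  s <- make_weekly(c(NA, NA, 5, 7, NA))
  cr <- crop_margins(s)
  expect_equal(cr$values, c(5, 7))
  expect_identical(cr$dates, s$dates[3:4])

  mid <- make_weekly(c(3, NA, 8, 1))
  expect_identical(crop_margins(mid), mid)
  expect_identical(crop_margins(crop_margins(s)), crop_margins(s))
  expect_error(crop_margins(make_weekly(rep(NA_real_, 4))), "no data")
})

test_that("inclusion rules: span, missing fraction, longest run", {
  # 160 weeks from Jan 2004 spans 37 calendar months: passes
  ok <- check_inclusion(make_weekly(runif(160, 1, 99)))
  expect_true(ok$passed)
  expect_identical(ok$n_months, 37L)
  expect_length(ok$reasons, 0)

  # 151 weeks spans 35 months: too short
  short <- check_inclusion(make_weekly(runif(151, 1, 99)))
  expect_false(short$passed)
  expect_identical(short$n_months, 35L)
  expect_identical(short$reasons, "min_span")

  # long series with an 11-week interior gap: run cap violated
  v <- runif(209, 1, 99); v[100:110] <- NA
  gap <- check_inclusion(make_weekly(c(1, v[-1])))
  expect_false(gap$passed)
  expect_identical(gap$longest_missing_run_weeks, 11L)
  expect_identical(gap$reasons, "max_run")

  # >10% missing scattered singly: fraction rule only
  v2 <- runif(300, 1, 99)
  v2[seq(5, 300, by = 8)] <- NA  # 37 isolated missing weeks = 12.3%
  v2[c(1, 300)] <- 50
  frac <- check_inclusion(make_weekly(v2))
  expect_false(frac$passed)
  expect_identical(frac$reasons, "max_missing")
})

test_that("linear interpolation fills interior gaps exactly", {
  expect_equal(interpolate_weekly(make_weekly(c(10, NA, 20)))$values,
               c(10, 15, 20))
  expect_equal(interpolate_weekly(make_weekly(c(10, NA, NA, 40)))$values,
               c(10, 20, 30, 40))
  # values on a line are reconstructed exactly after knocking out 20%
  line <- seq(5, 95, length.out = 100)
  holed <- line
  set.seed(8)
  holed[sample(2:99, 20)] <- NA
  out <- interpolate_weekly(make_weekly(holed))
  expect_equal(out$values, line, tolerance = 1e-12)
  expect_false(any(out$missing))
  expect_error(interpolate_weekly(make_weekly(c(NA, 3, 4))), "crop_margins")
})

test_that("calendar-weighted aggregation conserves constants and bounds", {
  const <- make_weekly(rep(42, 60))
  m <- aggregate_to_monthly(const)
  expect_equal(m$values, rep(42, length(m$values)), tolerance = 1e-12)

  set.seed(4)
  w <- make_weekly(runif(80, 0, 100))
  mm <- aggregate_to_monthly(w)
  expect_gte(min(mm$values), min(w$values))
  expect_lte(max(mm$values), max(w$values))
  idx <- mm$year * 12L + mm$month
  expect_true(all(diff(idx) == 1L))
})

test_that("margin months with sparse day coverage are dropped", {
  # first week starts Jan 25: January is covered by only 7 days
  w <- weekly_series(seq(as.Date("2004-01-25"), by = 7, length.out = 30),
                     rep(10, 30))
  m <- aggregate_to_monthly(w)
  expect_identical(m$month[1], 2L)
  m2 <- aggregate_to_monthly(w, min_days = 5)
  expect_identical(m2$month[1], 1L)
})

test_that("the full preparation pipeline yields an analyzable monthly series", {
  sp <- gen_spec(n_weeks = 170, seed = 13, missing_fraction = 0.05,
                 max_missing_run = 4, coefficients = list(ar = 0.6))
  prep <- prepare_series(generate_search_series(sp))
  expect_identical(prep$category, "incomplete")
  expect_true(prep$inclusion$passed)
  expect_false(any(prep$weekly$missing))
  expect_s3_class(prep$monthly, "monthly_series")
  expect_gte(length(prep$monthly), 36)
})
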