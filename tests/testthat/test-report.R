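fake_cell <- function(r, band = 0.25, region = "SYN", term = "t1",
                      stratum = "total", term_class = "pro_suicide") {
  stopifnot(length(r) == 7)
  tb <- data.frame(lag = -3:3, r = r, n_pairs = 60, band = band,
                   significant = abs(r) > band)
  list(region = region, term = term, stratum = stratum,
       term_class = term_class,
       ccf = structure(list(table = tb, x_label = term, y_label = stratum,
                            region = region, alpha = 0.05),
                       class = "ccf_result"),
       classification = NULL, model_spec = "(1,0,0)", error = NULL)
}

test_that("idealized patterns follow the stratum magnitudes, sign and step rule", {
  young <- build_ideal("pro_suicide", "younger")
  expect_equal(young$expected_r, c(0.20, 0.30, 0.40, 0.50))
  expect_identical(young$lags, -3:0)

  prev <- build_ideal("prevention", "total")
  expect_equal(prev$expected_r, c(-0.10, -0.20, -0.30, -0.40))
  expect_identical(prev$expected_sign, -1)

  for (cls in c("pro_suicide", "depression", "prevention"))
    for (st in c("total", "younger", "older", "older_men", "older_women",
                 "men", "women")) {
      p <- build_ideal(cls, st)
      expect_equal(diff(p$expected_r), rep(0.10 * p$expected_sign, 3))
      expect_true(p$zero_at_positive_lags)
    }
  expect_equal(abs(build_ideal("depression", "women")$expected_r[4]), 0.50)
  expect_equal(abs(build_ideal("depression", "men")$expected_r[4]), 0.40)
  expect_error(build_ideal("pro_suicide", "unknown"), "stratum")
})

test_that("grid arithmetic counts term x stratum x lag cells exactly", {
  one <- analysis_design(data.frame(label = "a", class = "pro_suicide",
                                    region = "SYN"), strata = "total")
  expect_identical(count_grid(one), 7L)

  none <- analysis_design(data.frame(label = character(), class = character(),
                                     region = character()))
  expect_identical(count_grid(none), 0L)

  two <- analysis_design(
    data.frame(label = c("a", "b"), class = "pro_suicide", region = "SYN"),
    strata = c("total", "younger"),
    extra_strata = list(b = c("men", "women")))
  expect_identical(count_grid(two), (2L * 2L + 2L) * 7L)
})

test_that("the published term inventory is intact", {
  tt <- retained_terms()
  expect_identical(nrow(tt), 29L)
  expect_true(all(tt$class %in% c("pro_suicide", "prevention", "depression")))
  expect_identical(sum(tt$region == "US"), 19L)
  expect_identical(anyDuplicated(paste(tt$region, tt$label)), 0L)
})

test_that("summary statistics: bins at the printed boundaries, rates, concordance", {
  cells <- list(
    fake_cell(c(0.55, 0, 0, 0, 0, 0, 0.02), term = "t1"),
    fake_cell(c(-0.35, 0.05, 0, 0, 0, 0, 0.01), term = "t2"),
    fake_cell(c(0.15, 0.04, 0, 0, 0, 0, 0.03), term = "t3"),
    fake_cell(c(0.05, 0.02, 0, 0, 0, 0, 0.04), term = "t4"))
  sm <- summarize_cells(cells)
  expect_identical(sm$n_coefficients, 28L)
  # one value in each bin, everything else negligible
  expect_identical(unname(sm$bin_counts),
                   c(1L, 1L, 1L, 25L))
  expect_equal(sm$pct_significant, 100 * 2 / 28)
  expect_identical(sm$n_failed_cells, 0L)

  # boundary values land in the lower-inclusive bins
  b <- summarize_cells(list(fake_cell(c(0.50, 0.30, 0.10, 0.0999, 0, 0, 0),
                                      band = 0.6)))$bin_counts
  expect_identical(unname(b), c(1L, 1L, 1L, 4L))

  # a cell matching its idealized pattern at every significant lag scores 1
  perfect <- fake_cell(c(0.20, 0.30, 0.40, 0.50, 0, 0, 0), band = 0.25,
                       stratum = "younger")
  expect_equal(summarize_cells(list(perfect))$concordance$concordance, 1)
  # wrong-signed and positive-lag significance score -1
  wrong <- fake_cell(c(0, -0.4, 0, 0, 0, 0.4, 0), band = 0.25,
                     stratum = "younger")
  expect_equal(summarize_cells(list(wrong))$concordance$concordance, -1)
  # no significant lags: neutral score
  quiet <- fake_cell(rep(0.01, 7))
  expect_equal(summarize_cells(list(quiet))$concordance$concordance, 0)
})

test_that("heat-map export is long-format, ordered, and round-trips", {
  cells <- list(fake_cell(c(0.3, 0, 0, 0, 0, 0, 0)),
                fake_cell(rep(0, 7), term = "t2", stratum = "younger"))
  df <- export_heatmap(cells)
  expect_identical(nrow(df), 14L)
  expect_identical(names(df)[1:4], c("region", "term", "stratum", "lag"))

  path <- tempfile(fileext = ".csv")
  export_heatmap(cells, path)
  back <- read.csv(path)
  expect_equal(back$r, df$r, tolerance = 1e-12)
  expect_identical(back$lag, df$lag)

  design <- analysis_design(
    data.frame(label = c("t1", "t2"), class = "pro_suicide", region = "SYN"),
    strata = "total")
  expect_identical(nrow(df), count_grid(design))
})

test_that("run_grid executes the design and recovers an injected association", {
  design <- analysis_design(
    data.frame(label = c("t1", "t2", "t3"), class = "pro_suicide",
               region = "SYN"),
    strata = c("total", "younger"))
  spec <- gen_spec(arima_orders = c(1, 0, 0, 0, 1, 1), season_length = 12,
                   coefficients = list(ar = 0.5, sma = -0.6), n_weeks = 84)
  store <- synthetic_store(design, spec, seed = 77,
                           injected = list(term = "t2", stratum = "younger",
                                           transfer = transfer_spec(0.6, -2)))
  expect_setequal(names(store$terms), c("SYN:t1", "SYN:t2", "SYN:t3"))
  expect_setequal(names(store$outcomes$SYN), c("total", "younger"))

  cells <- run_grid(store, design,
                    grid = list(arima_spec(1, 0, 0, 0, 1, 1, 12)),
                    with_outliers = FALSE)
  expect_length(cells, 6)
  expect_true(all(vapply(cells, function(c) is.null(c$error), TRUE)))
  inj <- Filter(function(c) c$term == "t2" && c$stratum == "younger", cells)[[1]]
  tb <- inj$ccf$table
  expect_identical(tb$lag[which.max(abs(tb$r))], -2L)
  expect_true(tb$significant[tb$lag == -2])

  # a store with a missing series yields a cell-level error, not a crash
  store2 <- store
  store2$terms[["SYN:t3"]] <- NULL
  cells2 <- run_grid(store2, design,
                     grid = list(arima_spec(1, 0, 0, 0, 1, 1, 12)),
                     with_outliers = FALSE)
  bad <- Filter(function(c) c$term == "t3", cells2)
  expect_true(all(vapply(bad, function(c) !is.null(c$error), TRUE)))
})
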