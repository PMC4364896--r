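test_that("regression recovers generating parameters on noise-free data", {
  temps <- gen_temperatures(60, mean = 16.4, sd = 0.7, seed = 11)
  # offset 0 keeps the back-transform exactly invertible (no flooring)
  sf <- gen_seedfall(temps, a = 0.33, b = 0.97, residual_sd = 0, log_offset = 0)
  # suppress summary.lm's perfect-fit warning: exact fit is the point here
  reg <- suppressWarnings(
    fit_seedfall_regression(temps, sf, mode = "dT", log_offset = 0))
  expect_equal(reg$a, 0.33, tolerance = 1e-8)
  expect_equal(reg$b, 0.97, tolerance = 1e-8)
  expect_gt(reg$r_squared, 1 - 1e-10)
  expect_lt(reg$residual_sd, 1e-8)
})

test_that("constant seedfall gives zero slope and r-squared", {
  temps <- gen_temperatures(20, seed = 2)
  sf <- annual_series(temps$year[3:20], rep(4, 18))
  reg <- fit_seedfall_regression(temps, sf, mode = "dT")
  expect_equal(reg$b, 0, tolerance = 1e-12)
  expect_equal(reg$r_squared, 0, tolerance = 1e-12)
})

test_that("T-mode regression uses the previous summer's temperature", {
  temps <- gen_temperatures(40, seed = 3)
  # construct seedfall exactly log-linear in T_{y-1}
  tprev <- annual_series(temps$year[2:40], temps$value[1:39])
  sf <- annual_series(tprev$year, 10 ^ (-18.61 + 1.14 * tprev$value))
  reg <- suppressWarnings(
    fit_seedfall_regression(temps, sf, mode = "T", log_offset = 0))
  expect_equal(reg$a, -18.61, tolerance = 1e-6)
  expect_equal(reg$b, 1.14, tolerance = 1e-6)
})

test_that("prediction back-transforms the linear predictor with flooring", {
  reg <- make_regression(a = 0.33, b = 0.97, log_offset = 0)
  temps <- annual_series(1970:1974, rep(16, 5))  # delta-T = 0 everywhere
  f <- predict_seedfall(reg, temps)
  expect_equal(f$value, rep(10 ^ 0.33, 3), tolerance = 1e-12)

  flat <- make_regression(a = 0.5, b = 0, log_offset = 1)
  temps2 <- gen_temperatures(10, seed = 4)
  expect_equal(var(predict_seedfall(flat, temps2)$value), 0)

  # monotone in delta-T for b > 0: rising then falling temperatures
  temps3 <- annual_series(1970:1980, c(15, 15.2, 15.6, 16.2, 17, 16.8, 16.4,
                                       16.2, 16.1, 16.05, 16.0))
  dt <- compute_delta_t(temps3)
  f3 <- predict_seedfall(reg, temps3)
  expect_identical(order(f3$value), order(dt$value))
})

test_that("mast classification matches hand-computed standardized deviates", {
  s <- annual_series(2001:2005, c(0, 0, 0, 0, 100))
  mr <- classify_masts(s)
  expect_equal(mr$ad, c(rep(-0.4472136, 4), 1.7888544), tolerance = 1e-6)
  expect_equal(mr$ad_thres, 0.4472136, tolerance = 1e-6)
  expect_equal(sum(mr$flags), 1)
  expect_equal(mr$years[mr$flags], 2005L)

  sym <- classify_masts(annual_series(1:3, c(1, 2, 3)))
  expect_equal(sym$ad_thres, 0)
  expect_equal(sum(sym$flags), 1)  # only the year with AD > 0

  expect_error(classify_masts(annual_series(1:4, rep(2, 4))), "constant")
})

test_that("mast classification is invariant under affine seedfall rescaling", {
  set.seed(42)
  f <- abs(rnorm(30, 10, 8))
  a <- classify_masts(annual_series(1:30, f))
  b <- classify_masts(annual_series(1:30, 3.7 * f + 11))
  expect_equal(a$ad, b$ad, tolerance = 1e-12)
  expect_identical(a$flags, b$flags)
})

test_that("climate thresholds are minima of the lagged predictors over masts", {
  temps <- annual_series(1970:1980, c(16, 15.5, 17.2, 16.1, 15.8, 17.5, 16.0,
                                      16.3, 17.1, 15.9, 16.2))
  # force known mast years 1972 and 1975
  sf <- annual_series(1972:1980, c(50, 1, 1, 60, 1, 2, 1.5, 1, 2.5))
  mr <- classify_masts(sf)
  expect_true(all(c(1972L, 1975L) %in% mr$years[mr$flags]))
  mr <- climate_thresholds(mr, temps)
  mast_years <- mr$years[mr$flags]
  tprev <- temps$value[match(mast_years - 1, temps$year)]
  dts <- compute_delta_t(temps)
  dtv <- dts$value[match(mast_years, dts$year)]
  expect_equal(mr$t_thres, min(tprev))
  expect_equal(mr$dt_thres, min(dtv))

  none <- classify_masts(annual_series(1:5, c(5, 4, 6, 5.5, 4.5)))
  none$flags[] <- FALSE
  expect_error(climate_thresholds(none, temps), "no mast years")
})

test_that("interval statistics agree with brute force on all short sequences", {
  for (n in 2:10) {
    for (code in 0:(2^n - 1)) {
      flags <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
      got <- mast_interval_stats(flags)
      want <- brute_interval_stats(flags)
      expect_equal(got$prop_single, want$prop_single)
      expect_equal(got$prop_double, want$prop_double)
      expect_equal(got$mean_gap, want$mean_gap)
    }
  }
})

test_that("interval statistics handle the documented worked cases", {
  s <- mast_interval_stats(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(s$prop_single, 2 / 6)
  expect_equal(s$prop_double, 0)
  expect_equal(s$mean_gap, 5)

  all_true <- mast_interval_stats(rep(TRUE, 8))
  expect_equal(all_true$prop_single, 1)
  expect_equal(all_true$prop_double, 7 / 8)
  expect_equal(all_true$mean_gap, 1)

  expect_true(is.na(mast_interval_stats(c(FALSE, TRUE, FALSE))$mean_gap))
})

test_that("scenario adjustment matches reference moments on the overlap", {
  ref <- gen_temperatures(43, mean = 16.4, sd = 0.7, seed = 5, start_year = 1968)
  # biased scenario: cooler, damped, with a trend, longer record
  scen_raw <- gen_temperatures(133, mean = 15.1, sd = 0.4, seed = 6,
                               start_year = 1968)
  scen_raw$value <- scen_raw$value + 0.01 * (seq_len(133) - 1)
  scen <- annual_series(scen_raw$year, scen_raw$value)
  adj <- adjust_scenario(scen, ref)
  overlap <- intersect(adj$year, ref$year)
  expect_equal(mean(adj$value[match(overlap, adj$year)]),
               mean(ref$value[match(overlap, ref$year)]), tolerance = 1e-9)
  expect_equal(sd(adj$value[match(overlap, adj$year)]),
               sd(ref$value[match(overlap, ref$year)]), tolerance = 1e-9)
  # idempotence: adjusting the adjusted series is the identity
  adj2 <- adjust_scenario(adj, ref)
  expect_equal(adj2$value, adj$value, tolerance = 1e-12)
})

test_that("scenario adjustment removes a pure mean shift", {
  ref <- gen_temperatures(20, seed = 7)
  scen <- annual_series(ref$year, ref$value + 2)
  adj <- adjust_scenario(scen, ref)
  expect_equal(adj$value, ref$value, tolerance = 1e-12)
  ident <- adjust_scenario(ref, ref)
  expect_equal(ident$value, ref$value, tolerance = 1e-12)
  flat <- annual_series(ref$year, rep(1, 20))
  expect_error(adjust_scenario(flat, ref), "zero scenario variance")
})

test_that("distribution checks flag serial correlation and not i.i.d. noise", {
  alt <- annual_series(1:50, rep(c(1, -1), 25))
  chk <- distribution_checks(alt, comparison = alt)
  expect_equal(chk$ks$statistic, 0)
  expect_lt(chk$ljung_box$p_value[1], 1e-6)

  hits <- 0
  for (s in 1:20) {
    iid <- gen_temperatures(1000, seed = 100 + s)
    lb <- distribution_checks(iid)$ljung_box
    if (lb$p_value[1] > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
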