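test_that("carbon unit conversion follows the molar arithmetic", {
  ts <- seq(as.POSIXct("2015-06-01 00:30", tz = "UTC"), by = 1800,
            length.out = 48)
  tab <- data.frame(timestamp = ts, NEE = rep(-10, 48),
                    GPP_NT = rep(12, 48), Reco_NT = rep(2, 48),
                    TA = 15, Prec = 0)
  daily <- daily_aggregate(tab)
  expect_equal(nrow(daily), 1)
  expect_equal(daily$nep, 10 * 1800 * 48 * 12.011e-6, tolerance = 1e-12)
  expect_true(daily$complete)
  # missing half-hours flag the day and exclude it from budgets
  tab2 <- tab
  tab2$NEE[5] <- NA
  expect_false(daily_aggregate(tab2)$complete)
})

test_that("annual budget equals the sum of daily sums and closes NEP identity", {
  sim <- sim_clean_year()
  e0 <- fit_e0(sim$data)
  p <- partition_nighttime(sim$data, e0,
                           estimate_rref_series(sim$data, e0))
  daily <- daily_aggregate(p)
  b <- period_budget(daily, "year", year = 2015)
  expect_equal(b$nep, sum(daily$nep[daily$complete]), tolerance = 1e-9)
  expect_equal(b$nep, b$gpp - b$reco, tolerance = 1e-9)
  m6 <- period_budget(daily, "month", year = 2015, month = 6)
  expect_equal(m6$n_days, 30)
  expect_error(period_budget(daily, "year", year = 1999), "not covered")
})

test_that("growing-season budgets and u* scenarios run end to end", {
  sim <- sim_clean_year()
  e0 <- fit_e0(sim$data)
  p <- partition_nighttime(sim$data, e0,
                           estimate_rref_series(sim$data, e0))
  daily <- daily_aggregate(p)
  td <- transition_dates(fit_double_logistic(
    simulate_gcc(sim$config, noise_sd = 0, frac_low = 0, frac_spike = 0)))
  gs <- period_budget(daily, "growing_season", year = 2015, transition = td)
  expect_equal(gs$n_days,
               ceiling(td$eos) - floor(td$sos) + 1)
  yr <- period_budget(daily, "year", year = 2015)
  expect_lt(gs$gpp, yr$gpp)     # season is a subset of the year
  expect_gt(gs$gpp, 0.8 * yr$gpp)  # but holds almost all the uptake
  # threshold scenarios reprocess the record per u* quantile
  sc <- budget_scenarios(sim$data,
                         thresholds = c(q50 = sim$config$true_ustar_threshold))
  expect_equal(sc$scenario, "q50")
  expect_equal(sc$year, 2015)
  expect_equal(sc$nep, sc$gpp - sc$reco, tolerance = 1e-9)
})

test_that("monthly light-response tables cover the requested groups", {
  sim <- sim_clean_year()
  e0 <- fit_e0(sim$data)
  p <- partition_nighttime(sim$data, e0,
                           estimate_rref_series(sim$data, e0))
  lt <- light_response_table(p, year_sets = list(all = 2015), months = 6:7)
  expect_equal(nrow(lt), 2)
  expect_true(all(lt$alpha > 0))
  expect_true(all(lt$gpp_ref < lt$gpp_max))
})

test_that("composites reduce to the single year they contain", {
  sim <- sim_clean_year()
  e0 <- fit_e0(sim$data)
  p <- partition_nighttime(sim$data, e0,
                           estimate_rref_series(sim$data, e0))
  cp <- composites(p, groups = list(only = 2015))
  daily <- daily_aggregate(p)
  jun <- mean(daily$nep[format(daily$date, "%m") == "06"])
  expect_equal(cp$monthly$nep[cp$monthly$month == 6], jun)
  # diurnal bins average back to the period mean
  doy <- as.integer(format(p$timestamp, "%j"))
  sel <- doy %in% 110:300
  expect_equal(mean(cp$diurnal$nee), mean(p$NEE[sel]), tolerance = 1e-9)
  expect_error(composites(p, groups = list(none = integer())), "empty")
})

test_that("flux tables survive a CSV round trip and reject bad input", {
  sim <- sim_noisy_year()
  tab <- sim$data[1:200, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(tab, path)
  back <- read_flux_csv(path)
  expect_equal(back$NEE, tab$NEE, tolerance = 1e-6)
  expect_equal(back$ustar, tab$ustar, tolerance = 1e-6)
  expect_equal(back$timestamp, tab$timestamp)
  # malformed timestamp is rejected with its row number
  lines <- readLines(path)
  lines[5] <- sub("^[^,]*,", "not-a-time,", lines[5])
  writeLines(lines, path)
  expect_error(read_flux_csv(path), "row 4")
})

test_that("published site tables reproduce the drought summary arithmetic", {
  st <- site_summary_stats()
  expect_equal(st$mean_annual_nep, 362, tolerance = 0.5)
  expect_equal(st$pre_drought_mean_nep, 367.33, tolerance = 0.5)
  expect_equal(st$nep_reduction_legacy_pct, 25.4, tolerance = 0.5)
  expect_equal(st$gs_elongation_days, 19)
  expect_equal(st$gs_precip_share_drought_pct, 43, tolerance = 0.2)
  expect_equal(st$gpp_ref_ratio_pct, 74.9, tolerance = 0.5)
  # the published budgets close the NEP = GPP - Reco identity to rounding
  b <- site_annual_budgets()
  expect_lt(max(abs(b$nep - (b$gpp - b$reco))), 1.5)
})
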