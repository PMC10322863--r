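test_that("green chromatic coordinate handles edge cases and compositing", {
  rgb <- data.frame(date = as.Date("2016-06-01"),
                    R = c(0, 50), G = c(80, 50), B = c(0, 50))
  g <- compute_gcc(rgb)
  # pure green -> 1; grey -> 1/3; daily value is the 90th percentile
  expect_equal(g$gcc, unname(quantile(c(1, 1 / 3), 0.9)))
  # grey day plus a greener midday subset: daily value follows the subset
  rgb2 <- data.frame(date = as.Date("2016-06-02"),
                     R = c(rep(90, 8), rep(80, 2)),
                     G = c(rep(90, 8), rep(110, 2)),
                     B = c(rep(90, 8), rep(80, 2)))
  g2 <- compute_gcc(rgb2)
  expect_gt(g2$gcc, 1 / 3 + 0.01)
  # all-zero pixels are missing, negatives rejected
  expect_true(is.na(compute_gcc(data.frame(date = as.Date("2016-06-03"),
                                           R = 0, G = 0, B = 0))$gcc))
  expect_error(compute_gcc(data.frame(date = as.Date("2016-06-03"),
                                      R = -1, G = 2, B = 3)), "negative")
})

test_that("greenness filters remove artefacts but keep clean data", {
  cfg <- sim_config(seed = 41, years = 2016)
  clean <- simulate_gcc(cfg, noise_sd = 0, frac_low = 0, frac_spike = 0)
  fc <- filter_gcc(clean)
  expect_equal(nrow(fc), nrow(clean))
  # the stated low-illumination threshold
  one <- clean
  one$gcc[100] <- 0.15
  f1 <- filter_gcc(one)
  expect_false((as.Date("2016-01-01") + 99) %in% f1$date)
  # labelled injection: >= 90% of spikes removed, <= 1% of clean points lost
  g <- simulate_gcc(cfg, noise_sd = 0.005, frac_low = 0, frac_spike = 0.05,
                    spike_size = 0.1)
  fg <- filter_gcc(g)
  spikes_left <- sum(g$date[g$is_spike] %in% fg$date)
  expect_lte(spikes_left, 0.1 * sum(g$is_spike))
  clean_lost <- sum(!(g$date[!g$is_spike] %in% fg$date))
  expect_lte(clean_lost, 0.01 * sum(!g$is_spike))
})

test_that("double-logistic fit recovers the generator parameters", {
  cfg <- sim_config(seed = 42, years = 2016)
  pp <- cfg$pheno_params
  g0 <- simulate_gcc(cfg, noise_sd = 0, frac_low = 0, frac_spike = 0)
  fit <- fit_double_logistic(g0)
  expect_equal(fit$b, pp$baseline, tolerance = 1e-3)
  expect_equal(fit$a, pp$amplitude, tolerance = 1e-3)
  expect_equal(fit$t1, pp$t1, tolerance = 1e-3)
  expect_equal(fit$t2, pp$t2, tolerance = 1e-3)
  # residuals uncorrelated with fitted values on clean data
  g <- simulate_gcc(cfg, noise_sd = 0.005, frac_low = 0, frac_spike = 0)
  f2 <- fit_double_logistic(g)
  expect_lt(abs(cor(f2$gcc - f2$fitted, f2$fitted)), 0.1)
  # flat series is degenerate
  flat <- data.frame(doy = 1:366, gcc = rep(0.32, 366))
  expect_error(fit_double_logistic(flat), "degenerate")
})

test_that("spring date recovery within 3 days across noisy replicates", {
  errs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 500 + s, years = 2016)
    g <- simulate_gcc(cfg, noise_sd = 0.005, frac_low = 0, frac_spike = 0)
    fit_double_logistic(g)$t1 - cfg$pheno_params$t1
  }, numeric(1))
  expect_lt(max(abs(errs)), 3)
})

test_that("curvature-change transition dates have the stated geometry", {
  cfg <- sim_config(seed = 43, years = 2016)
  g0 <- simulate_gcc(cfg, noise_sd = 0, frac_low = 0, frac_spike = 0)
  fit <- fit_double_logistic(g0)
  td <- transition_dates(fit)
  expect_lt(td$sos, fit$t1)
  expect_gt(td$eos, fit$t2)
  expect_equal(td$length, td$eos - td$sos)
  # symmetric curve: dates mirror about the mid-season
  sym <- list(b = 0.3, a = 0.1, t1 = 120, c1 = 0.12, t2 = 280, c2 = 0.12)
  curve <- data.frame(doy = 1:366,
                      gcc = double_logistic(1:366, sym$b, sym$a, sym$t1,
                                            sym$c1, sym$t2, sym$c2))
  fs <- fit_double_logistic(curve)
  ts <- transition_dates(fs)
  mid <- (fs$t1 + fs$t2) / 2
  expect_lt(abs((mid - ts$sos) - (ts$eos - mid)), 0.2)
})

test_that("analytic curvature matches a finite-difference oracle", {
  fit <- structure(list(b = 0.32, a = 0.1, t1 = 120, c1 = 0.15,
                        t2 = 290, c2 = 0.10), class = "pheno_fit")
  t <- seq(80, 330, by = 0.5)
  h <- 1e-4
  g <- function(t) double_logistic(t, fit$b, fit$a, fit$t1, fit$c1,
                                   fit$t2, fit$c2)
  g1 <- (g(t + h) - g(t - h)) / (2 * h)
  g2 <- (g(t + h) - 2 * g(t) + g(t - h)) / h^2
  kap_num <- g2 / (1 + g1^2)^1.5
  kap_ana <- fluxlegacy:::.dl_curvature(t, fit)
  expect_lt(max(abs(kap_num - kap_ana)), 1e-6)
})

test_that("refit uncertainty is zero without residuals and reproducible", {
  cfg <- sim_config(seed = 44, years = 2016)
  g0 <- simulate_gcc(cfg, noise_sd = 0, frac_low = 0, frac_spike = 0)
  fit <- fit_double_logistic(g0)
  un <- date_uncertainty(fit, n = 10, seed = 1)
  expect_equal(un$sos_sd, 0, tolerance = 1e-6)
  expect_equal(un$eos_sd, 0, tolerance = 1e-6)
  g <- simulate_gcc(cfg, noise_sd = 0.005, frac_low = 0, frac_spike = 0)
  f2 <- fit_double_logistic(g)
  u1 <- date_uncertainty(f2, n = 20, seed = 9)
  u2 <- date_uncertainty(f2, n = 20, seed = 9)
  expect_identical(attr(u1, "draws"), attr(u2, "draws"))
  expect_gt(u1$sos_sd, 0)
})

test_that("growing-season length is recovered within 4 days from noisy data", {
  cfg <- sim_config(seed = 45, years = 2016)
  g0 <- simulate_gcc(cfg, noise_sd = 0, frac_low = 0, frac_spike = 0)
  truth <- transition_dates(fit_double_logistic(g0))
  g <- simulate_gcc(cfg, noise_sd = 0.005, frac_low = 0.03,
                    frac_spike = 0.02)
  td <- transition_dates(fit_double_logistic(filter_gcc(g)))
  expect_lt(abs(td$length - truth$length), 4)
})
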