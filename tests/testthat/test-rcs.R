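test_that("knots land on the default quantiles and respect ties", {
  set.seed(61)
  x <- runif(10000)
  expect_equal(place_knots(x, 3), quantile(x, c(0.1, 0.5, 0.9),
                                           names = FALSE),
               tolerance = 1e-12)
  expect_lt(max(abs(place_knots(x, 3) - c(0.1, 0.5, 0.9))), 0.02)
  expect_error(place_knots(x, 2), "3, 4 or 5")
  expect_error(place_knots(x, 6), "3, 4 or 5")
  # duplicated data leave the knots unchanged
  expect_equal(place_knots(c(x, x), 4), place_knots(x, 4))
  expect_error(place_knots(1:10, 3), "distinct values")
})

test_that("restricted basis is linear in the tails and matches the textbook formula", {
  kn <- c(-1, 0, 2)
  x <- seq(-5, 6, length.out = 100)
  B <- rcs_basis(x, kn)
  expect_equal(ncol(B), 2)
  # independent truncated-power construction for k = 3
  p3 <- function(u) pmax(u, 0)^3
  ref <- (p3(x - kn[1]) -
            p3(x - kn[2]) * (kn[3] - kn[1]) / (kn[3] - kn[2]) +
            p3(x - kn[3]) * (kn[2] - kn[1]) / (kn[3] - kn[2])) /
    (kn[3] - kn[1])^2
  expect_equal(unname(B[, 2]), ref)
  # second differences vanish outside the boundary knots
  xl <- seq(-8, -1.2, by = 0.1); xr <- seq(2.2, 9, by = 0.1)
  for (xx in list(xl, xr)) {
    Bt <- rcs_basis(xx, kn)
    f <- Bt %*% c(0.7, -1.3)
    expect_lt(max(abs(diff(diff(f)))), 1e-8)
  }
  # nesting: with zero spline coefficients the model is plain OLS
  set.seed(62)
  xx <- runif(300); y <- 1 + 2 * xx + rnorm(300, 0, 0.1)
  d <- data.frame(date = as.Date("2015-01-01") + 0:299, x = xx, GPP = y)
  m <- rcs_fit(d, "GPP", "x", k = 3)
  ols <- coef(lm(y ~ xx))
  # the fitted curve should be close to the OLS line where data live
  expect_lt(max(abs(predict(m, data.frame(x = c(0.2, 0.5, 0.8))) -
                      (ols[1] + ols[2] * c(0.2, 0.5, 0.8)))), 0.05)
})

test_that("an exactly representable response is fitted to machine precision", {
  set.seed(63)
  x <- runif(400, 0, 10)
  kt <- place_knots(x, 4)
  B <- rcs_basis(x, kt)
  y <- drop(2 + B %*% c(0.5, 3, -2))
  d <- data.frame(date = as.Date("2015-01-01") + 0:399, x = x, GPP = y)
  m <- rcs_fit(d, "GPP", "x", k = 4, knots = list(x = kt))
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_lt(max(abs(m$y - m$fitted)), 1e-8)
  # AIC identity from stored likelihood and parameter count
  expect_equal(m$aic, 2 * m$n_par - 2 * m$logLik)
  # collinear columns are named
  d$x2 <- d$x
  expect_error(rcs_fit(d, "GPP", c("x", "x2"), k = 3), "collinear")
})

test_that("Wald chi-square equals df times the nested-model F statistic", {
  set.seed(64)
  n <- 400
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  a = runif(n, 0, 10), b = runif(n, 0, 5))
  d$GPP <- 1 + 0.4 * d$a + sin(d$b) + rnorm(n, 0, 0.3)
  m <- rcs_fit(d, "GPP", c("a", "b"), k = 4)
  for (p in c("a", "b")) {
    imp <- feature_importance(m, p)
    S <- m$index[[p]]
    rss0 <- sum(qr.resid(qr(m$X[, -S, drop = FALSE]), m$y)^2)
    Fstat <- ((rss0 - m$rss) / length(S)) / (m$rss / (m$n - m$p))
    expect_lt(abs(imp$chi2 - length(S) * Fstat), 1e-6)
    expect_equal(imp$df, length(S))
    expect_equal(imp$importance, imp$chi2 - imp$df)
    expect_true(imp$nonlinearity >= 0 && imp$nonlinearity <= 1)
  }
  # a purely linear predictor has a small nonlinearity share
  set.seed(65)
  n2 <- 1000
  d2 <- data.frame(date = as.Date("2015-01-01") + 0:(n2 - 1),
                   a = runif(n2, 0, 10))
  d2$GPP <- 2 + 0.5 * d2$a + rnorm(n2, 0, 0.05)
  m2 <- rcs_fit(d2, "GPP", "a", k = 4)
  expect_lt(feature_importance(m2, "a")$nonlinearity, 0.1)
})

test_that("null predictors have chi-square near their degrees of freedom", {
  set.seed(66)
  n <- 150
  chis <- replicate(200, {
    d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                    a = runif(n), b = runif(n))
    d$GPP <- 1 + 2 * d$a + rnorm(n, 0, 0.5)   # b has no effect
    feature_importance(rcs_fit(d, "GPP", c("a", "b"), k = 3), "b")$chi2
  })
  # E[chi2] = df * (n-p)/(n-p-2) under the null; close to df = 2
  expect_lt(abs(mean(chis) - 2), 0.4)
})

test_that("AIC knot selection is parsimonious and deterministic", {
  picks <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 300
    d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                    a = runif(n, 0, 10))
    d$GPP <- 1 + 0.5 * d$a + rnorm(n, 0, 0.4)
    select_knots(d, "GPP", "a")$k
  }, numeric(1))
  expect_gte(mean(picks == 3), 0.8)
  # strong curvature prefers more knots at low noise
  set.seed(67)
  n <- 600
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  a = runif(n, 0, 10))
  d$GPP <- sin(d$a) + rnorm(n, 0, 0.05)
  expect_gte(select_knots(d, "GPP", "a")$k, 5)
  # deterministic given the data
  expect_identical(select_knots(d, "GPP", "a")$k,
                   select_knots(d, "GPP", "a")$k)
})

test_that("partial dependence is additive and flat for absent predictors", {
  set.seed(68)
  n <- 500
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  a = runif(n, 0, 10), b = runif(n, 0, 5))
  d$GPP <- 0.4 * d$a + sin(d$b) + rnorm(n, 0, 0.2)
  m <- rcs_fit(d, "GPP", c("a", "b"), k = 4)
  pd <- partial_dependence(m, c("a", "b"), grid_sizes = c(10, 10))
  # additive: the surface is the outer sum of its univariate margins
  mat <- matrix(pd$pd, 10, 10)
  recon <- outer(mat[, 1], mat[1, ] - mat[1, 1], "+")
  expect_lt(max(abs(mat - recon)), 1e-8)
  expect_false(any(pd$extrapolated))
})

test_that("yearly metrics behave at their fixed points", {
  set.seed(69)
  n <- 730
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  a = runif(n, 0, 10))
  d$GPP <- 1 + 0.5 * d$a
  m <- rcs_fit(d, "GPP", "a", k = 3)     # exact fit: linear truth
  ym <- yearly_metrics(m)
  expect_equal(ym$rmse, rep(0, nrow(ym)), tolerance = 1e-10)
  expect_equal(ym$mpe, rep(0, nrow(ym)), tolerance = 1e-8)
  expect_equal(ym$adj_r2, rep(1, nrow(ym)), tolerance = 1e-10)
  # sign convention: predictions at twice the observations give MPE -100%
  m2 <- m
  m2$fitted <- 2 * m$y
  ym2 <- yearly_metrics(m2)
  expect_equal(ym2$mpe, rep(-100, nrow(ym2)), tolerance = 1e-8)
})

test_that("model comparison has a zero fixed point and penalizes noise", {
  set.seed(70)
  n <- 400
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  a = runif(n, 0, 10))
  d$GPP <- 1 + 0.5 * d$a + rnorm(n, 0, 0.3)
  m <- rcs_fit(d, "GPP", "a", k = 3)
  cmp <- compare_models(m, m)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$delta_adj_r2, 0)
  expect_true(all(cmp$years$delta_mpe == 0))
  # pure-noise extra predictors raise AIC in expectation
  daics <- replicate(30, {
    dd <- d
    dd$noise <- rnorm(n)
    full <- rcs_fit(dd, "GPP", c("a", "noise"), k = 3)
    full$aic - m$aic
  })
  expect_gt(mean(daics), 0)
})
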