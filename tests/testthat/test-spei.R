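# independent oracle: numerically integrate the solar constant over the day
.ra_numeric <- function(lat, doy) {
  gsc <- 0.0820 * 24 * 60              # MJ m-2 d-1 at normal incidence
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  h <- seq(-pi, pi, length.out = 20001)
  cosz <- pmax(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h), 0)
  gsc * dr * mean(cosz)
}

test_that("extraterrestrial radiation matches a numeric solar-geometry oracle", {
  for (case in list(c(0, 80), c(52, 172), c(-35, 20), c(60, 300))) {
    expect_equal(extraterrestrial_radiation(case[1], case[2]),
                 .ra_numeric(case[1], case[2]), tolerance = 1e-3)
  }
  expect_equal(extraterrestrial_radiation(0, 80), 37.8, tolerance = 0.01)
  grid <- expand.grid(lat = seq(-60, 60, 10), doy = seq(1, 361, 30))
  expect_true(all(extraterrestrial_radiation(grid$lat, grid$doy) > 0))
  # hemispheric symmetry holds for the geometric part (the Earth-Sun
  # distance factor differs between the solstices)
  dr <- function(doy) 1 + 0.033 * cos(2 * pi / 365 * doy)
  r1 <- extraterrestrial_radiation(52, 172) / dr(172)
  r2 <- extraterrestrial_radiation(-52, 355) / dr(355)
  expect_lt(abs(r1 / r2 - 1), 0.01)
  expect_error(extraterrestrial_radiation(70, 100), "polar")
})

test_that("Hargreaves PET vanishes at its formula zeros and matches by hand", {
  clim <- data.frame(date = as.Date("2015-06-21"), tmin = 12, tmax = 26,
                     tmean = 19, latitude = 52)
  ra <- extraterrestrial_radiation(52, 172)
  expect_equal(pet_hargreaves(clim),
               0.0023 * (ra / 2.45) * (19 + 17.8) * sqrt(26 - 12))
  clim$tmean <- -17.8
  expect_equal(pet_hargreaves(clim), 0)
  clim2 <- data.frame(date = as.Date("2015-06-21"), tmin = 15, tmax = 15,
                      tmean = 15, latitude = 52)
  expect_equal(pet_hargreaves(clim2), 0)
})

test_that("aggregated water balance equals a brute-force window sum", {
  set.seed(31)
  p <- rgamma(400, 0.7, 0.2)
  pet <- runif(400, 0, 6)
  expect_equal(water_balance(p, pet, 1), p - pet)
  # constant difference
  expect_equal(water_balance(rep(5, 50), rep(2, 50), 10),
               c(rep(NA, 9), rep(30, 41)))
  # brute force at k = 30
  d30 <- water_balance(p, pet, 30)
  brute <- sapply(30:400, function(t) sum((p - pet)[(t - 29):t]))
  expect_equal(d30[30:400], brute)
  expect_true(all(is.na(d30[1:29])))
})

test_that("log-logistic PWM fit recovers known parameters", {
  set.seed(32)
  F <- runif(10000)
  x <- -100 + 50 * (F / (1 - F))^(1 / 3)
  p <- fit_loglogistic(x)
  expect_lt(abs(p$shape / 3 - 1), 0.05)
  expect_lt(abs(p$scale / 50 - 1), 0.05)
  expect_lt(abs((p$location + 100) / 100), 0.05)
  # translation equivariance
  p2 <- fit_loglogistic(x + 100)
  expect_equal(p2$shape, p$shape, tolerance = 1e-8)
  expect_equal(p2$scale, p$scale, tolerance = 1e-8)
  expect_equal(p2$location, p$location + 100, tolerance = 1e-6)
  # the fitted CDF puts the sample median near 0.5
  x1k <- x[1:1000]
  p3 <- fit_loglogistic(x1k)
  expect_lt(abs(ploglogistic(median(x1k), p3) - 0.5), 0.05)
  # left-skewed samples fit through the reflected orientation
  set.seed(33)
  y <- 100 - rgamma(1000, 2, 0.05)
  p4 <- fit_loglogistic(y)
  expect_true(isTRUE(p4$reflected))
  expect_lt(abs(ploglogistic(median(y), p4) - 0.5), 0.05)
  Fy <- ploglogistic(sort(y), p4)
  expect_true(all(diff(Fy) >= -1e-12))   # monotone CDF
  expect_error(fit_loglogistic(rep(1, 30)), "degenerate")
  expect_error(fit_loglogistic(rnorm(10)), "20 samples")
})

test_that("SPEI standardizes to ~N(0,1) over a 30+ year reference", {
  clim <- climate_30y()
  sp <- spei(clim, scales = c(30, 365))
  for (k in c(30, 365)) {
    s <- sp[sp$scale == k, ]
    doy <- as.integer(format(s$date, "%j"))
    m <- tapply(s$spei, doy, mean, na.rm = TRUE)
    sdv <- tapply(s$spei, doy, sd, na.rm = TRUE)
    expect_lt(abs(mean(m, na.rm = TRUE)), 0.05)
    expect_gt(mean(sdv, na.rm = TRUE), 0.9)
    expect_lt(mean(sdv, na.rm = TRUE), 1.1)
    expect_true(all(abs(s$spei) <= 3.29, na.rm = TRUE))
  }
})

test_that("the pooled median maps to SPEI 0 and categories follow thresholds", {
  set.seed(34)
  F <- runif(500)
  x <- 10 + 30 * (F / (1 - F))^(1 / 4)
  p <- fit_loglogistic(x)
  expect_lt(abs(qnorm(ploglogistic(median(x), p))), 0.1)
  expect_equal(as.character(spei_category(c(-0.5, -1, -1.5, -2, 0.7))),
               c("none", "moderate", "severe", "extreme", "none"))
  expect_true(is.na(spei_category(NA_real_)))
})

test_that("raising any in-window water input never lowers SPEI", {
  clim <- climate_30y()[1:4000, ]
  # freeze the reference so both runs use identical fitted distributions
  ref <- 1981:1989
  sp1 <- spei(clim, scales = 90, reference = ref)
  clim2 <- clim
  i <- 3950    # in 1991, inside the window of the series end
  clim2$precip[i] <- clim2$precip[i] + 40
  sp2 <- spei(clim2, scales = 90, reference = ref)
  later <- sp1$date >= clim$date[i] & sp1$date <= clim$date[i] + 89
  cmp <- sp2$spei[later] - sp1$spei[later]
  expect_true(all(cmp >= -1e-8, na.rm = TRUE))
})
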