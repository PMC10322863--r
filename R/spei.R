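#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation from standard solar geometry (inverse
#' relative Earth-Sun distance, solar declination, sunset hour angle), as
#' used by temperature-based evapotranspiration formulas.
#'
#' @param latitude latitude in decimal degrees; |latitude| < 66.5 (polar
#'   day/night not handled).
#' @param doy day of year (1-366); vectorised, recycled against `latitude`.
#' @return radiation in MJ m-2 d-1.
#' @export
#' @examples
#' extraterrestrial_radiation(52, 172)
extraterrestrial_radiation <- function(latitude, doy) {
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes (|lat| >= 66.5) are not supported", call. = FALSE)
  if (any(doy < 1 | doy > 366)) stop("doy must be in 1..366", call. = FALSE)
  gsc <- 0.0820                                     # MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Hargreaves potential evapotranspiration
#'
#' `PET = 0.0023 * (Ra / lambda) * (tmean + 17.8) * sqrt(tmax - tmin)` with
#' latent heat of vaporisation lambda = 2.45 MJ kg-1; negative values are
#' clipped to zero. A temperature-only formulation, appropriate for daily
#' climate records without radiation or humidity measurements.
#'
#' @param climate data.frame with `date`, `tmin`, `tmax`, `tmean` (C) and
#'   `latitude` (degrees).
#' @return PET in mm d-1, `NA` where temperature is missing.
#' @export
pet_hargreaves <- function(climate) {
  stopifnot(all(c("date", "tmin", "tmax", "tmean", "latitude") %in%
                  names(climate)))
  bad <- !is.na(climate$tmin) & !is.na(climate$tmax) &
    climate$tmin > climate$tmax
  if (any(bad)) stop("tmin > tmax in ", sum(bad), " rows", call. = FALSE)
  doy <- as.integer(format(climate$date, "%j"))
  ra <- extraterrestrial_radiation(climate$latitude, pmin(doy, 365))
  pet <- 0.0023 * (ra / 2.45) * (climate$tmean + 17.8) *
    sqrt(pmax(climate$tmax - climate$tmin, 0))
  pmax(pet, 0)
}

#' Aggregated climatic water balance
#'
#' Trailing sum over the `k` days ending at each date of the daily water
#' balance P - PET. The first `k - 1` days, and any day whose window
#' contains a missing member, are `NA`.
#'
#' @param precip daily precipitation (mm).
#' @param pet daily potential evapotranspiration (mm).
#' @param k aggregation scale in days (>= 1).
#' @return the aggregated balance D_k (mm), same length as the inputs.
#' @export
water_balance <- function(precip, pet, k) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  d <- precip - pet
  if (k == 1) return(d)
  as.numeric(zoo::rollsumr(zoo::zoo(d), k, fill = NA))
}

#' Fit a three-parameter log-logistic distribution
#'
#' Fits by unbiased probability-weighted moments (PWM). The CDF is
#' `F(x) = [1 + (scale / (x - location))^shape]^-1` for `x > location`.
#' The PWM solution requires positive sample skew; for left-skewed samples
#' (common in aggregated climatic water balances, whose dry tail is long)
#' the mirrored sample `-x` is fitted instead and the distribution is
#' marked `reflected`, keeping the standardization within the log-logistic
#' family in both orientations.
#'
#' @param x numeric sample (>= 20 values, non-degenerate).
#' @return a list with `shape`, `scale`, `location`, `reflected`.
#' @export
fit_loglogistic <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) stop("need at least 20 samples", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate (zero-variance) sample",
                              call. = FALSE)
  fit1 <- .ll_pwm(x)
  if (!is.null(fit1)) return(c(fit1, reflected = FALSE))
  # left-skewed samples: fit the mirrored data, X = -Y with Y log-logistic
  fit2 <- .ll_pwm(-x)
  if (is.null(fit2))
    stop("log-logistic PWM fit failed (shape <= 1 in both orientations)",
         call. = FALSE)
  c(fit2, reflected = TRUE)
}

.ll_pwm <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  # unbiased PWM  w_s = mean of x_(i) * C(n-i, s) / C(n-1, s)
  w0 <- mean(xs)
  w1 <- sum(xs * (n - i) / (n - 1)) / n
  w2 <- sum(xs * (n - i) * (n - i - 1) / ((n - 1) * (n - 2))) / n
  shape <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  if (!is.finite(shape) || shape <= 1) return(NULL)
  g12 <- gamma(1 + 1 / shape) * gamma(1 - 1 / shape)
  scale <- (w0 - 2 * w1) * shape / g12
  location <- w0 - scale * g12
  list(shape = shape, scale = scale, location = location)
}

#' Log-logistic cumulative distribution function
#'
#' @param x quantiles.
#' @param p parameter list from [fit_loglogistic()].
#' @return probabilities; 0 for `x <= location`.
#' @export
ploglogistic <- function(x, p) {
  if (isTRUE(p$reflected)) {
    xr <- -x
    out <- rep(1, length(x))
    pos <- !is.na(xr) & xr > p$location
    out[pos] <- 1 -
      1 / (1 + (p$scale / (xr[pos] - p$location))^p$shape)
  } else {
    out <- numeric(length(x))
    pos <- !is.na(x) & x > p$location
    out[pos] <- 1 / (1 + (p$scale / (x[pos] - p$location))^p$shape)
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Daily standardized precipitation-evapotranspiration index
#'
#' For each aggregation scale and calendar day, the climatic water balance
#' D_k is pooled over the reference years within a +/- 15-day window, a
#' three-parameter log-logistic distribution is fitted by probability
#' weighted moments, and the index is the standard normal quantile of the
#' fitted cumulative probability: `SPEI = qnorm(F(D_k))`. Probabilities are
#' clamped to [0.0005, 0.9995] so |SPEI| <= 3.29. Negative values flag drier
#' than the reference climatology; categories follow the usual thresholds
#' (<= -1 moderate, <= -1.5 severe, <= -2 extreme drought, the last
#' corresponding to a cumulative occurrence probability of about 2.3%).
#' Feb 29 is pooled with Feb 28.
#'
#' @param climate daily climate table (`date`, `precip`, `tmin`, `tmax`,
#'   `tmean`, `latitude`).
#' @param scales integer vector of aggregation scales in days; the default
#'   grid spans 5 to 365 days.
#' @param reference integer vector of reference years (default: all years in
#'   the record).
#' @param min_pool minimum pooled sample per calendar-day fit; scales whose
#'   pools are smaller are skipped with a warning.
#' @return a long `data.frame` of class `spei_series`: `date`, `scale`,
#'   `spei`, `category`.
#' @export
spei <- function(climate,
                 scales = c(5, 10, 15, 20, 30, 45, 60, 90, 120, 150,
                            180, 240, 300, 365),
                 reference = NULL, min_pool = 20L) {
  stopifnot(all(c("date", "precip") %in% names(climate)))
  climate <- climate[order(climate$date), ]
  pet <- pet_hargreaves(climate)
  years <- as.integer(format(climate$date, "%Y"))
  if (is.null(reference)) reference <- sort(unique(years))
  if (!all(reference %in% years))
    stop("reference period not contained in the record", call. = FALSE)
  # calendar day with Feb 29 mapped onto Feb 28
  md <- format(climate$date, "%m-%d")
  md[md == "02-29"] <- "02-28"
  cday <- match(md, sort(unique(md)))
  n <- nrow(climate)
  in_ref <- years %in% reference

  out <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    k <- scales[si]
    dk <- water_balance(climate$precip, pet, k)
    # pool indices per calendar day: +/- 15 positions cyclically is not
    # appropriate across record edges; use +/- 15 actual days
    spei_k <- rep(NA_real_, n)
    ref_idx <- which(in_ref & !is.na(dk))
    skipped <- FALSE
    for (cd in sort(unique(cday))) {
      rows <- which(cday == cd & !is.na(dk))
      if (!length(rows)) next
      # reference pool: same calendar day +/- 15 days in reference years
      anchor <- which(cday == cd & in_ref)
      pool <- unique(unlist(lapply(anchor, function(i)
        seq(max(1L, i - 15L), min(n, i + 15L)))))
      pool <- pool[in_ref[pool] & !is.na(dk[pool])]
      if (length(pool) < min_pool) { skipped <- TRUE; break }
      fit <- tryCatch(fit_loglogistic(dk[pool]), error = function(e) NULL)
      if (is.null(fit)) next
      p <- ploglogistic(dk[rows], fit)
      p <- pmin(pmax(p, 0.0005), 0.9995)
      spei_k[rows] <- stats::qnorm(p)
    }
    if (skipped) {
      warning("scale ", k, " skipped: reference pool below ", min_pool,
              " samples", call. = FALSE)
      next
    }
    spei_k <- pmin(pmax(spei_k, -3.29), 3.29)
    out[[si]] <- data.frame(date = climate$date, scale = k, spei = spei_k,
                            category = spei_category(spei_k))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("all scales skipped", call. = FALSE)
  class(res) <- c("spei_series", "data.frame")
  res
}

#' Drought category of an SPEI value
#'
#' @param x SPEI values.
#' @return factor with levels none/moderate/severe/extreme.
#' @export
spei_category <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- "none"
  out[ok & x <= -1] <- "moderate"
  out[ok & x <= -1.5] <- "severe"
  out[ok & x <= -2] <- "extreme"
  factor(out, levels = c("none", "moderate", "severe", "extreme"))
}
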