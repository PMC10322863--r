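#' Standardize a daily series by calendar day across years
#'
#' For each calendar day, values are z-transformed using the mean and
#' standard deviation over the available years at that day. Days with fewer
#' than two years, or zero variance, return NA.
#'
#' @param daily data.frame with `date` and the value column.
#' @param var name of the value column (default the second column).
#' @return the input with a `z` column added.
#' @export
standardize_by_doy <- function(daily, var = setdiff(names(daily), "date")[1]) {
  yr <- as.integer(format(daily$date, "%Y"))
  if (length(unique(yr)) < 2L)
    stop("standardization needs at least two years", call. = FALSE)
  doy <- as.integer(format(daily$date, "%j"))
  x <- daily[[var]]
  mu <- tapply(x, doy, mean, na.rm = TRUE)
  sdv <- tapply(x, doy, stats::sd, na.rm = TRUE)
  nyr <- tapply(!is.na(x), doy, sum)
  key <- as.character(doy)
  z <- (x - mu[key]) / sdv[key]
  z[nyr[key] < 2 | sdv[key] == 0 | !is.finite(z)] <- NA_real_
  daily$z <- as.numeric(z)
  daily
}

#' Drought fingerprint: rolling flux-SPEI correlation
#'
#' Correlates a standardized daily flux with SPEI across aggregation scales
#' and days of year. The cell for day-of-year d and scale k pools all pairs
#' whose DOY lies within the centred window (default 5 days, i.e.
#' [d-2, d+2]) across all years — about `window * n_years` pairs — and
#' reports the Pearson correlation; cells with fewer than `min_pairs`
#' complete pairs are NA.
#'
#' @param z data.frame with `date` and `z` from [standardize_by_doy()].
#' @param spei long SPEI table from [spei()].
#' @param window odd window width in days (default 5).
#' @param doy_range rows of the fingerprint (default growing season,
#'   DOY 110-300).
#' @param min_pairs minimum complete pairs per cell (default 10).
#' @return an object of class `fingerprint` — a long data.frame
#'   (`doy`, `scale`, `r`, `n`).
#' @export
rolling_correlation <- function(z, spei, window = 5L,
                                doy_range = 110:300, min_pairs = 10L) {
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  half <- (window - 1L) %/% 2L
  scales <- sort(unique(spei$scale))
  zdoy <- as.integer(format(z$date, "%j"))
  out <- list()
  for (k in scales) {
    sk <- spei[spei$scale == k, ]
    sv <- sk$spei[match(z$date, sk$date)]
    for (d in doy_range) {
      sel <- zdoy >= d - half & zdoy <= d + half
      zz <- z$z[sel]; ss <- sv[sel]
      ok <- !is.na(zz) & !is.na(ss)
      n <- sum(ok)
      r <- if (n >= min_pairs)
        suppressWarnings(stats::cor(zz[ok], ss[ok])) else NA_real_
      out[[length(out) + 1L]] <- c(doy = d, scale = k, r = r, n = n)
    }
  }
  res <- as.data.frame(do.call(rbind, out))
  class(res) <- c("fingerprint", "data.frame")
  res
}

#' Pooled regression over a fingerprint window
#'
#' Pools all (SPEI, z) pairs within a DOY range and a range of aggregation
#' scales, across years and scales, and fits ordinary least squares
#' `z ~ SPEI`. With both axes standardized the slope approximates the mean
#' correlation over the window.
#'
#' @inheritParams rolling_correlation
#' @param doys day-of-year range to pool (e.g. `121:151` for May).
#' @param scales aggregation scales to pool (e.g. `c(30, 45, 60, 90)`).
#' @param min_pairs minimum pooled pairs (default 20).
#' @return list with `slope`, `intercept`, `r`, `n` and the pooled `pairs`
#'   data.frame.
#' @export
window_summary <- function(z, spei, doys, scales, min_pairs = 20L) {
  zdoy <- as.integer(format(z$date, "%j"))
  zin <- z[zdoy %in% doys, c("date", "z")]
  sin <- spei[spei$scale %in% scales &
                as.integer(format(spei$date, "%j")) %in% doys, ]
  pairs <- merge(sin, zin, by = "date")
  pairs <- pairs[!is.na(pairs$z) & !is.na(pairs$spei), ]
  if (nrow(pairs) < min_pairs)
    stop("fewer than ", min_pairs, " pooled pairs in window", call. = FALSE)
  fit <- stats::lm(z ~ spei, data = pairs)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(pairs$spei, pairs$z),
       n = nrow(pairs), pairs = pairs)
}

#' Default fingerprint summary windows
#'
#' The four canonical DOY-by-scale rectangles: short- (30-90 d) and
#' long-scale (270-365 d) SPEI in May (DOY 121-151) and in August
#' (DOY 213-243).
#'
#' @return named list of lists with `doys` and `scales`.
#' @export
fingerprint_windows <- function() {
  list(
    may_short = list(doys = 121:151, scales = c(30, 45, 60, 90)),
    may_long = list(doys = 121:151, scales = c(300, 365)),
    aug_short = list(doys = 213:243, scales = c(30, 45, 60, 90)),
    aug_long = list(doys = 213:243, scales = c(300, 365))
  )
}
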