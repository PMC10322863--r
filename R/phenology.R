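#' Green chromatic coordinate from RGB digital numbers
#'
#' `Gcc = G / (R + G + B)` per image; when several images per day are
#' supplied the daily value is the 90th percentile of the within-day values,
#' which suppresses illumination-driven variance.
#'
#' @param rgb data.frame with `timestamp` (or `date`) and per-image ROI mean
#'   digital numbers `R`, `G`, `B` (all >= 0, not all zero).
#' @return data.frame with `date` and daily `gcc` (NA where all channels
#'   are zero for every image of the day).
#' @export
compute_gcc <- function(rgb) {
  stopifnot(all(c("R", "G", "B") %in% names(rgb)))
  if (any(rgb$R < 0 | rgb$G < 0 | rgb$B < 0, na.rm = TRUE))
    stop("negative digital numbers", call. = FALSE)
  total <- rgb$R + rgb$G + rgb$B
  gcc <- ifelse(total > 0, rgb$G / total, NA_real_)
  date <- if ("date" %in% names(rgb)) as.Date(rgb$date)
          else as.Date(rgb$timestamp, tz = "UTC")
  agg <- tapply(gcc, date, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else unname(stats::quantile(v, 0.9))
  })
  data.frame(date = as.Date(names(agg)), gcc = as.numeric(agg),
             row.names = NULL)
}

#' Filter a greenness series
#'
#' Removes (1) low-illumination values, Gcc < 0.2; (2) outliers more than 3
#' scaled median absolute deviations away from a 15-day running median; and
#' (3), when per-day brightness is supplied, days whose total brightness
#' (R+G+B) deviates more than 50% from its 15-day running median.
#'
#' @param series data.frame with `date`, `gcc`, optionally `brightness`.
#' @return the series with rows that failed a filter removed; counts per
#'   rule are attached as attribute `removed`.
#' @export
filter_gcc <- function(series) {
  keep <- !is.na(series$gcc)
  low <- keep & series$gcc < 0.2
  keep <- keep & !low

  run_med <- function(x) {
    # 15-day centered running median, NA-tolerant
    as.numeric(zoo::rollapply(zoo::zoo(x), 15,
                              function(v) stats::median(v, na.rm = TRUE),
                              fill = NA, partial = TRUE))
  }
  g <- ifelse(keep, series$gcc, NA)
  med <- run_med(g)
  resid <- series$gcc - med
  # noise scale from the MAD of first differences: robust to spikes and
  # unaffected by the slow seasonal signal
  s <- stats::mad(diff(g[keep]), na.rm = TRUE) / sqrt(2)
  out <- keep & !is.na(resid) & s > 0 & abs(resid) > 3 * s
  keep <- keep & !out

  bright <- rep(FALSE, nrow(series))
  if ("brightness" %in% names(series)) {
    bmed <- run_med(ifelse(keep, series$brightness, NA))
    bright <- keep & !is.na(series$brightness) & !is.na(bmed) &
      abs(series$brightness - bmed) > 0.5 * bmed
    keep <- keep & !bright
  }

  if (mean(!keep) > 0.8)
    warning("more than 80% of greenness points removed by filtering",
            call. = FALSE)
  res <- series[keep, , drop = FALSE]
  attr(res, "removed") <- c(low_illumination = sum(low), outlier = sum(out),
                            scene_illumination = sum(bright))
  res
}

#' Fit a double-logistic curve to a greenness series
#'
#' Least-squares fit of [double_logistic()] with multi-start initialisation
#' from curve quantiles (half-amplitude crossings for the inflection dates,
#' a small grid of slopes) using `minpack.lm::nlsLM` at convergence
#' tolerance 1e-8.
#'
#' @param series filtered data.frame with `date` (or `doy`) and `gcc`;
#'   needs >= 60 valid days spanning both limbs of the season.
#' @return an object of class `pheno_fit` with elements `b`, `a`, `t1`,
#'   `c1`, `t2`, `c2`, `sigma` (residual sd), `doy`, `gcc`, `fitted`.
#' @export
fit_double_logistic <- function(series) {
  doy <- if ("doy" %in% names(series)) series$doy
         else as.integer(format(series$date, "%j"))
  ok <- !is.na(doy) & !is.na(series$gcc)
  doy <- doy[ok]; gcc <- series$gcc[ok]
  if (length(doy) < 60L)
    stop("need at least 60 valid days", call. = FALSE)
  q <- stats::quantile(gcc, c(0.05, 0.95))
  a0 <- q[[2]] - q[[1]]
  if (a0 < 1e-6 || stats::sd(gcc) < 1e-10)
    stop("degenerate series: no seasonal amplitude", call. = FALSE)
  half <- q[[1]] + a0 / 2
  above <- gcc > half
  t1_0 <- if (any(above)) min(doy[above]) else stats::quantile(doy, 0.3)
  t2_0 <- if (any(above)) max(doy[above]) else stats::quantile(doy, 0.7)
  d <- data.frame(t = doy, y = gcc)
  best <- NULL
  for (c0 in c(0.05, 0.1, 0.2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ double_logistic(t, b, a, t1, c1, t2, c2), data = d,
        start = list(b = q[[1]], a = a0, t1 = t1_0, c1 = c0,
                     t2 = t2_0, c2 = c0),
        lower = c(-Inf, 1e-6, 1, 1e-4, 1, 1e-4),
        upper = c(Inf, Inf, 366, 5, 366, 5),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-8,
                                             ptol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("double-logistic fit failed from all starting points ",
         "(starts: t1 = ", round(t1_0), ", t2 = ", round(t2_0), ")",
         call. = FALSE)
  co <- as.list(stats::coef(best$fit))
  if (co$t1 >= co$t2)
    stop("fitted inflection dates are not ordered (t1 >= t2)", call. = FALSE)
  structure(list(
    b = co$b, a = co$a, t1 = co$t1, c1 = co$c1, t2 = co$t2, c2 = co$c2,
    sigma = sqrt(best$rss / max(length(doy) - 6, 1)),
    doy = doy, gcc = gcc,
    fitted = double_logistic(doy, co$b, co$a, co$t1, co$c1, co$t2, co$c2)
  ), class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf(
    "<pheno_fit> b %.3f a %.3f | t1 %.1f (c1 %.3f) t2 %.1f (c2 %.3f) | sigma %.4f\n",
    x$b, x$a, x$t1, x$c1, x$t2, x$c2, x$sigma))
  invisible(x)
}

# analytic first/second derivative and curvature of the double logistic
.dl_curvature <- function(t, fit) {
  l1 <- 1 / (1 + exp(-fit$c1 * (t - fit$t1)))
  l2 <- 1 / (1 + exp(fit$c2 * (t - fit$t2)))
  g1 <- fit$a * (fit$c1 * l1 * (1 - l1) - fit$c2 * l2 * (1 - l2))
  g2 <- fit$a * (fit$c1^2 * l1 * (1 - l1) * (1 - 2 * l1) +
                 fit$c2^2 * l2 * (1 - l2) * (1 - 2 * l2))
  g2 / (1 + g1^2)^1.5
}

#' Transition dates from curvature extrema
#'
#' The curvature of the fitted double logistic is computed analytically and
#' its rate of change evaluated on a 0.1-day grid. The start of season (SOS)
#' is the first local maximum of the curvature change rate on the rising
#' limb (before `t1 + 3/c1`); the end of season (EOS) is the last local
#' minimum on the falling limb (after `t2 - 3/c2`). Season length is
#' `EOS - SOS`.
#'
#' @param fit a [fit_double_logistic()] result.
#' @return an object of class `transition_dates`: `sos`, `eos` (DOY),
#'   `length` (days), plus `sos_sd`/`eos_sd` (NA until
#'   [date_uncertainty()] is run).
#' @export
transition_dates <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  grid <- seq(1, 366, by = 0.1)
  kap <- .dl_curvature(grid, fit)
  dk <- diff(kap) / diff(grid)                  # rate of change of curvature
  tm <- (grid[-1] + grid[-length(grid)]) / 2
  locmax <- which(diff(sign(diff(dk))) == -2) + 1L
  locmin <- which(diff(sign(diff(dk))) == 2) + 1L
  rise <- tm[locmax][tm[locmax] < fit$t1 + 3 / fit$c1]
  fall <- tm[locmin][tm[locmin] > fit$t2 - 3 / fit$c2]
  if (!length(rise) || !length(fall))
    stop("no curvature-change extremum found on the rising/falling limb",
         call. = FALSE)
  sos <- rise[1]; eos <- fall[length(fall)]
  structure(list(sos = sos, eos = eos, length = eos - sos,
                 sos_sd = NA_real_, eos_sd = NA_real_),
            class = "transition_dates")
}

#' @export
print.transition_dates <- function(x, ...) {
  cat(sprintf("<transition_dates> SOS %.1f (+/- %s) | EOS %.1f (+/- %s) | length %.1f d\n",
              x$sos, ifelse(is.na(x$sos_sd), "?", sprintf("%.1f", x$sos_sd)),
              x$eos, ifelse(is.na(x$eos_sd), "?", sprintf("%.1f", x$eos_sd)),
              x$length))
  invisible(x)
}

#' Transition-date uncertainty by residual resampling
#'
#' Repeats the double-logistic fit `n` times on the fitted curve plus
#' residuals resampled with replacement, and reports the standard deviation
#' of the resulting transition dates.
#'
#' @param fit a [fit_double_logistic()] result.
#' @param n number of refits (default 100).
#' @param seed integer seed.
#' @return a `transition_dates` object with `sos_sd` and `eos_sd` filled
#'   in; the refit dates are attached as attribute `draws`.
#' @export
date_uncertainty <- function(fit, n = 100L, seed = 1L) {
  stopifnot(inherits(fit, "pheno_fit"))
  base <- transition_dates(fit)
  resid <- fit$gcc - fit$fitted
  set.seed(seed)
  draws <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("sos", "eos")))
  fail <- 0L
  for (b in seq_len(n)) {
    y <- fit$fitted + sample(resid, length(resid), replace = TRUE)
    td <- tryCatch(
      transition_dates(fit_double_logistic(
        data.frame(doy = fit$doy, gcc = y))),
      error = function(e) NULL)
    if (is.null(td)) { fail <- fail + 1L; next }
    draws[b, ] <- c(td$sos, td$eos)
  }
  if (fail > 0.2 * n)
    warning(fail, " of ", n, " refits failed", call. = FALSE)
  base$sos_sd <- stats::sd(draws[, "sos"], na.rm = TRUE)
  base$eos_sd <- stats::sd(draws[, "eos"], na.rm = TRUE)
  attr(base, "draws") <- draws
  base
}
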