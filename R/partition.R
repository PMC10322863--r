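#' Estimate the Lloyd-Taylor temperature sensitivity E0
#'
#' Nighttime NEE is taken as ecosystem respiration and
#' `Reco(T) = Rref exp(E0 (1/(Tref - T0) - 1/(T - T0)))` is fitted by
#' nonlinear least squares in 15-day windows shifted by 5 days. Windows are
#' retained when they hold at least 6 records spanning a temperature range
#' of at least 5 C, yield E0 in [30, 450] K and a relative standard error
#' below 50%. The site E0 is the inverse-variance weighted mean of the
#' retained window estimates, which favours the windows with the lowest
#' relative standard error.
#'
#' @param table u*-filtered half-hourly table (`timestamp`, `NEE`, `TA`,
#'   `SW_IN`); only night rows (SW_IN < 10 W m-2) with data are used.
#' @param tref,t0 Lloyd-Taylor constants (C).
#' @return E0 in K, with the per-window estimates attached as attribute
#'   `windows`.
#' @export
fit_e0 <- function(table, tref = 15, t0 = -46.02) {
  night <- .night_rows(table)
  night <- night[!is.na(night$NEE) & !is.na(night$TA), ]
  if (nrow(night) == 0L) stop("no valid night records", call. = FALSE)
  t_day <- as.numeric(as.Date(night$timestamp, tz = "UTC"))
  t_day <- t_day - min(t_day)
  starts <- seq(0, max(t_day), by = 5)
  est <- lapply(starts, function(s) {
    d <- night[t_day >= s & t_day < s + 15, ]
    if (nrow(d) < 6L || diff(range(d$TA)) < 5) return(NULL)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        NEE ~ rref * exp(e0 * (1 / (tref - t0) - 1 / (TA - t0))),
        data = d, start = list(rref = max(mean(d$NEE), 0.1), e0 = 100),
        lower = c(0, 5), upper = c(Inf, 600),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    co <- summary(fit)$coefficients
    e0 <- co["e0", "Estimate"]; se <- co["e0", "Std. Error"]
    if (e0 < 30 || e0 > 450 || !is.finite(se) || se / abs(e0) >= 0.5)
      return(NULL)
    c(e0 = e0, rse = se / abs(e0))
  })
  est <- do.call(rbind, est[!vapply(est, is.null, logical(1))])
  if (is.null(est) || nrow(est) == 0L)
    stop("E0 not identifiable: no 15-day window met the retention rules ",
         "(>= 6 night records, TA range >= 5 C, E0 in [30, 450], ",
         "relative SE < 50%)", call. = FALSE)
  w <- 1 / pmax((est[, "rse"] * abs(est[, "e0"]))^2, 1e-12)
  structure(sum(est[, "e0"] * w) / sum(w), windows = est)
}

#' Time-varying reference respiration Rref(t)
#'
#' With E0 fixed, Rref is estimated in 7-day windows stepped by 4 days as a
#' regression through the origin of nighttime NEE on the Lloyd-Taylor
#' temperature term, then interpolated linearly to every half-hour.
#'
#' @inheritParams fit_e0
#' @param e0 fixed temperature sensitivity (K), e.g. from [fit_e0()].
#' @return numeric vector of Rref at every row of `table` (umol m-2 s-1).
#' @export
estimate_rref_series <- function(table, e0, tref = 15, t0 = -46.02) {
  night <- .night_rows(table)
  night <- night[!is.na(night$NEE) & !is.na(night$TA), ]
  if (nrow(night) == 0L) stop("no valid night records", call. = FALSE)
  tn <- as.numeric(night$timestamp)
  t0s <- min(as.numeric(table$timestamp))
  day <- (tn - t0s) / 86400
  starts <- seq(0, max(day), by = 4)
  fits <- lapply(starts, function(s) {
    sel <- day >= s & day < s + 7
    if (sum(sel) < 2L) return(NULL)
    f <- exp(e0 * (1 / (tref - t0) - 1 / (night$TA[sel] - t0)))
    rref <- sum(night$NEE[sel] * f) / sum(f * f)
    c(center = s + 3.5, rref = max(rref, 0))
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || nrow(fits) == 0L)
    stop("no window with enough night records for Rref", call. = FALSE)
  at <- (as.numeric(table$timestamp) - t0s) / 86400
  if (nrow(fits) == 1L) return(rep(fits[1, "rref"], nrow(table)))
  stats::approx(fits[, "center"], fits[, "rref"], xout = at, rule = 2)$y
}

#' Partition NEE into respiration and productivity (nighttime method)
#'
#' Ecosystem respiration is extrapolated to all half-hours with the
#' Lloyd-Taylor model (`Reco = Rref(t) exp(E0 (...))`), and GPP follows from
#' the budget identity `GPP = Reco - NEE`. GPP is computed for nighttime
#' rows as well (where it scatters around zero) and is not clipped; negative
#' values are flagged instead, so the identity `NEE + GPP - Reco = 0` holds
#' at every half-hour.
#'
#' @param table half-hourly table with gap-filled `NEE` (column `NEE_f` if
#'   present, else `NEE`) and complete `TA`.
#' @param e0 Lloyd-Taylor temperature sensitivity (K).
#' @param rref Rref(t) series from [estimate_rref_series()] (recycled if
#'   scalar).
#' @inheritParams fit_e0
#' @return the table with columns `Reco_NT`, `GPP_NT` and logical
#'   `GPP_NT_neg` added.
#' @export
partition_nighttime <- function(table, e0, rref, tref = 15, t0 = -46.02) {
  nee <- if ("NEE_f" %in% names(table)) table$NEE_f else table$NEE
  if (anyNA(table$TA))
    stop("TA contains missing values; gap-fill TA first", call. = FALSE)
  reco <- lloyd_taylor(table$TA, rref, e0, tref, t0)
  gpp <- reco - nee
  table$Reco_NT <- reco
  table$GPP_NT <- gpp
  table$GPP_NT_neg <- !is.na(gpp) & gpp < 0
  table
}

#' Michaelis-Menten light-response fit
#'
#' Fits the rectangular hyperbola
#' `GPP = alpha * PPFD * gpp_max / (alpha * PPFD + gpp_max)` to daytime
#' partitioned GPP by nonlinear least squares, and evaluates the reference
#' productivity at light saturation, PPFD = 2000 umol m-2 s-1. The apparent
#' quantum yield `alpha` is the initial slope; `gpp_max` the asymptote.
#'
#' @param table table with `GPP_NT`, `PPFD`, `SW_IN`; daytime rows
#'   (SW_IN >= 10 W m-2) are used.
#' @param group optional label stored with the fit (e.g. "Jul 2018").
#' @param min_records minimum number of daytime records (default 30).
#' @return an object of class `light_response_fit`: `alpha`, `gpp_max`,
#'   `gpp_ref` (GPP at PPFD 2000), `group`, `n`, `rmse`.
#' @export
fit_light_response <- function(table, group = NA_character_,
                               min_records = 30L) {
  d <- table[!is.na(table$SW_IN) & table$SW_IN >= 10 &
               !is.na(table$GPP_NT) & !is.na(table$PPFD), ]
  if (nrow(d) < min_records)
    stop("fewer than ", min_records, " daytime records in group ", group,
         call. = FALSE)
  a0 <- 0.05
  b0 <- max(stats::quantile(d$GPP_NT, 0.95), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      GPP_NT ~ alpha * PPFD * gpp_max / (alpha * PPFD + gpp_max),
      data = d, start = list(alpha = a0, gpp_max = b0),
      lower = c(1e-6, 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("light-response fit did not converge (starting values alpha = ",
           a0, ", gpp_max = ", signif(b0, 3), "): ", conditionMessage(e),
           call. = FALSE))
  co <- stats::coef(fit)
  alpha <- co[["alpha"]]; gpp_max <- co[["gpp_max"]]
  structure(list(
    alpha = alpha, gpp_max = gpp_max,
    gpp_ref = alpha * 2000 * gpp_max / (alpha * 2000 + gpp_max),
    group = group, n = nrow(d),
    rmse = sqrt(mean(stats::residuals(fit)^2))
  ), class = "light_response_fit")
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat(sprintf(
    "<light_response_fit> %s: alpha %.4f, gpp_max %.2f, gpp_ref(2000) %.2f (n=%d)\n",
    x$group, x$alpha, x$gpp_max, x$gpp_ref, x$n))
  invisible(x)
}

#' Monthly light-response table across year groups
#'
#' Fits [fit_light_response()] per month within each named set of years,
#' mirroring the tabulated seasonal comparison of drought and reference
#' years.
#'
#' @param table half-hourly table with `GPP_NT`, `PPFD`, `SW_IN`.
#' @param year_sets named list of integer year vectors.
#' @param months months to fit (default May-September).
#' @return tidy `data.frame` (month, year_set, alpha, gpp_max, gpp_ref, n);
#'   groups with too few records are skipped.
#' @export
light_response_table <- function(table, year_sets,
                                 months = 5:9) {
  yr <- as.integer(format(table$timestamp, "%Y"))
  mo <- as.integer(format(table$timestamp, "%m"))
  out <- list()
  for (set in names(year_sets)) {
    for (m in months) {
      d <- table[yr %in% year_sets[[set]] & mo == m, ]
      fit <- tryCatch(
        fit_light_response(d, group = sprintf("%02d-%s", m, set)),
        error = function(e) NULL)
      if (is.null(fit)) next
      out[[length(out) + 1L]] <- data.frame(
        month = m, year_set = set, alpha = fit$alpha,
        gpp_max = fit$gpp_max, gpp_ref = fit$gpp_ref, n = fit$n)
    }
  }
  do.call(rbind, out)
}
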