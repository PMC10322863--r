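#' Aggregate half-hourly fluxes to daily values
#'
#' Carbon fluxes are integrated as
#' `sum(umol m-2 s-1) * 1800 s * 12.011 ug umol-1 * 1e-6 -> gC m-2 d-1`
#' (molar mass of carbon, matching budgets quoted in gC); meteorological
#' variables are daily means, precipitation a daily sum. NEP = -NEE
#' (positive = net uptake). A day is `complete` when all 48 half-hours have
#' a filled NEE; incomplete days are flagged and excluded from budgets.
#'
#' @param table half-hourly table with `timestamp`, `GPP_NT`, `Reco_NT` and
#'   `NEE_f` (or `NEE`), plus met columns.
#' @return daily data.frame: `date`, `nep`, `gpp`, `reco` (gC m-2 d-1),
#'   met means, `prec` (mm), `n`, `complete`.
#' @export
daily_aggregate <- function(table) {
  nee <- if ("NEE_f" %in% names(table)) table$NEE_f else table$NEE
  umol_to_gc <- 1800 * 12.011e-6
  date <- as.Date(table$timestamp - 1, tz = "UTC")   # end-of-interval stamps
  f <- factor(date)
  sum_c <- function(x) tapply(x * umol_to_gc, f, sum)
  mean_c <- function(v) if (v %in% names(table))
    as.numeric(tapply(table[[v]], f, mean, na.rm = TRUE)) else NA_real_
  n <- as.integer(tapply(nee, f, length))
  out <- data.frame(
    date = as.Date(levels(f)),
    nep = -as.numeric(sum_c(nee)),
    gpp = if ("GPP_NT" %in% names(table))
      as.numeric(sum_c(table$GPP_NT)) else NA_real_,
    reco = if ("Reco_NT" %in% names(table))
      as.numeric(sum_c(table$Reco_NT)) else NA_real_,
    sw_in = mean_c("SW_IN"), ppfd = mean_c("PPFD"), ta = mean_c("TA"),
    vpd = mean_c("VPD"), h = mean_c("H"), le = mean_c("LE"),
    rn = mean_c("Rn"), swc_50 = mean_c("SWC_50"),
    prec = if ("Prec" %in% names(table))
      as.numeric(tapply(table$Prec, f, sum)) else NA_real_,
    n = n, row.names = NULL
  )
  out$complete <- out$n == 48L & !is.na(out$nep)
  out
}

#' Carbon and meteorology budget for a period
#'
#' Sums the daily carbon fluxes and precipitation and averages the
#' meteorological drivers over a year, a month, or the growing season of a
#' year (inclusive SOS-EOS bounds from greenness phenology). Met averages
#' carry the standard error of the mean of the daily values. Incomplete
#' days are excluded from carbon sums.
#'
#' @param daily daily table from [daily_aggregate()].
#' @param period `"year"`, `"month"` or `"growing_season"`.
#' @param year the calendar year of the period.
#' @param month month number (for `period = "month"`).
#' @param transition a [transition_dates()] object (for
#'   `period = "growing_season"`).
#' @return one-row data.frame with `nep`, `gpp`, `reco`, `prec` sums and
#'   met means +/- SE.
#' @export
period_budget <- function(daily, period = c("year", "month",
                                            "growing_season"),
                          year, month = NULL, transition = NULL) {
  period <- match.arg(period)
  yr <- as.integer(format(daily$date, "%Y"))
  sel <- yr == year
  if (period == "month") {
    if (is.null(month)) stop("`month` required", call. = FALSE)
    sel <- sel & as.integer(format(daily$date, "%m")) == month
  } else if (period == "growing_season") {
    if (is.null(transition))
      stop("`transition` dates required for the growing season",
           call. = FALSE)
    doy <- as.integer(format(daily$date, "%j"))
    sel <- sel & doy >= floor(transition$sos) & doy <= ceiling(transition$eos)
  }
  d <- daily[sel, , drop = FALSE]
  if (nrow(d) == 0L) stop("period not covered by the data", call. = FALSE)
  dc <- d[d$complete, , drop = FALSE]
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  data.frame(
    period = period, year = year,
    n_days = nrow(dc),
    nep = sum(dc$nep), gpp = sum(dc$gpp), reco = sum(dc$reco),
    prec = sum(d$prec, na.rm = TRUE),
    ta = mean(d$ta, na.rm = TRUE), ta_se = se(d$ta),
    vpd = mean(d$vpd, na.rm = TRUE), vpd_se = se(d$vpd),
    ppfd = mean(d$ppfd, na.rm = TRUE), ppfd_se = se(d$ppfd),
    h = mean(d$h, na.rm = TRUE), h_se = se(d$h),
    le = mean(d$le, na.rm = TRUE), le_se = se(d$le),
    rn = mean(d$rn, na.rm = TRUE), rn_se = se(d$rn)
  )
}

#' Annual budgets across u* threshold scenarios
#'
#' Re-runs filtering, gap-filling, partitioning and aggregation of a raw
#' half-hourly table at each supplied u* threshold (conventionally the
#' bootstrap q05/q50/q95) and reports the annual NEP/GPP/Reco per scenario,
#' giving the threshold-uncertainty range of the carbon budgets.
#'
#' @param table raw half-hourly flux table.
#' @param thresholds named numeric vector of u* thresholds (m s-1), e.g.
#'   `c(q05 = ..., q50 = ..., q95 = ...)`.
#' @return data.frame with one row per scenario and year.
#' @export
budget_scenarios <- function(table, thresholds) {
  out <- list()
  for (s in names(thresholds)) {
    proc <- process_fluxes(table, ustar_threshold = thresholds[[s]])
    daily <- daily_aggregate(proc)
    for (y in unique(as.integer(format(daily$date, "%Y")))) {
      b <- period_budget(daily, "year", year = y)
      out[[length(out) + 1L]] <- cbind(scenario = s, threshold =
                                         thresholds[[s]], b)
    }
  }
  do.call(rbind, out)
}

#' Monthly means, cumulative sums and mean diurnal cycles by year group
#'
#' Composites for contrasting drought and reference years: monthly means of
#' the daily fluxes, within-year cumulative sums, and the mean diurnal
#' cycle (48 half-hour bins) per group over a day-of-year window.
#'
#' @param halfhourly half-hourly table with partitioned fluxes.
#' @param groups named list of integer year vectors (must be non-empty).
#' @param doy_range vegetation-period window for the diurnal composite.
#' @return list with `monthly`, `cumulative` (daily), and `diurnal`.
#' @export
composites <- function(halfhourly, groups, doy_range = 110:300) {
  for (g in names(groups)) if (!length(groups[[g]]))
    stop("empty year group: ", g, call. = FALSE)
  daily <- daily_aggregate(halfhourly)
  yr_d <- as.integer(format(daily$date, "%Y"))
  mo_d <- as.integer(format(daily$date, "%m"))
  monthly <- list(); cumulative <- list(); diurnal <- list()
  yr_h <- as.integer(format(halfhourly$timestamp, "%Y"))
  doy_h <- as.integer(format(halfhourly$timestamp, "%j"))
  hh <- ((as.numeric(halfhourly$timestamp) / 1800 - 1) %% 48) + 1
  nee <- if ("NEE_f" %in% names(halfhourly)) halfhourly$NEE_f
         else halfhourly$NEE
  for (g in names(groups)) {
    dg <- daily[yr_d %in% groups[[g]] & daily$complete, ]
    mg <- stats::aggregate(dg[c("nep", "gpp", "reco", "h", "le")],
                           by = list(month = as.integer(format(dg$date,
                                                               "%m"))),
                           FUN = mean)
    monthly[[g]] <- cbind(group = g, mg)
    dg <- dg[order(dg$date), ]
    dg$doy <- as.integer(format(dg$date, "%j"))
    cums <- do.call(rbind, lapply(split(dg, format(dg$date, "%Y")),
      function(dy) {
        dy$cum_nep <- cumsum(dy$nep); dy
      }))
    cumulative[[g]] <- cbind(group = g,
                             cums[c("date", "doy", "nep", "cum_nep")])
    sel <- yr_h %in% groups[[g]] & doy_h %in% doy_range
    di <- data.frame(group = g, bin = sort(unique(hh)),
                     nee = as.numeric(tapply(nee[sel], hh[sel], mean,
                                             na.rm = TRUE)))
    diurnal[[g]] <- di
  }
  list(monthly = do.call(rbind, monthly),
       cumulative = do.call(rbind, cumulative),
       diurnal = do.call(rbind, diurnal))
}
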