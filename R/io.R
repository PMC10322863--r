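#' Write / read a half-hourly flux table as CSV
#'
#' Columns use the site's standard abbreviations (`NEE`, `H`, `LE`, `Rn`,
#' `G`, `u*`, `SW_IN`, `PPFD`, `TA`, `RH`, `VPD`, `Prec`, `SWC_50`).
#' Timestamps are end-of-interval local standard time (no DST), written as
#' `YYYY-MM-DD HH:MM`; missing values are empty fields.
#'
#' @param table flux table (internal column `ustar` maps to header `u*`).
#' @param path file path.
#' @return `write_flux_csv` returns `path` invisibly; `read_flux_csv`
#'   returns the table with `timestamp` parsed (POSIXct, UTC as the local
#'   standard clock) and `u*` renamed back to `ustar`.
#' @export
write_flux_csv <- function(table, path) {
  out <- table
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  names(out)[names(out) == "ustar"] <- "u*"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(raw))
    stop("schema violation: no `timestamp` column", call. = FALSE)
  ts <- as.POSIXct(raw$timestamp, tz = "UTC", format = "%Y-%m-%d %H:%M")
  bad <- which(is.na(ts) & !is.na(raw$timestamp) & nzchar(raw$timestamp))
  if (length(bad))
    stop("malformed timestamp at data row ", bad[1], ": `",
         raw$timestamp[bad[1]], "`", call. = FALSE)
  if (anyNA(ts)) stop("empty timestamps present", call. = FALSE)
  if (is.unsorted(ts, strictly = TRUE))
    stop("timestamps not strictly increasing", call. = FALSE)
  raw$timestamp <- ts
  names(raw)[names(raw) == "u*"] <- "ustar"
  num <- setdiff(names(raw), "timestamp")
  for (v in num) raw[[v]] <- as.numeric(raw[[v]])
  raw
}

#' Published annual and growing-season budgets of the study site
#'
#' Annual and growing-season sums of NEP/GPP/Reco (gC m-2) and
#' precipitation (mm), mean meteorology and greenness-derived
#' growing-season length as published for the mixed deciduous forest site
#' 'Hohes Holz' (DE-HoH, Central Germany) for 2015-2020, bundled as a
#' plain-text table. These serve as reference inputs for site-level
#' summary statistics and for benchmarking pipeline output.
#'
#' @return data.frame with columns `year`, `period`
#'   (`full`/`growing_season`), `nep`, `gpp`, `reco` (gC m-2), `h`, `le`,
#'   `rn` (W m-2), `ppfd` (umol m-2 s-1), `ta` (C), `prec` (mm), `vpd`
#'   (hPa), `gs_length` (days; full-year rows NA).
#' @export
site_annual_budgets <- function() {
  utils::read.csv(system.file("extdata", "dehoh_annual_budgets.csv",
                              package = "fluxlegacy"))
}

#' Published monthly light-response parameters of the study site
#'
#' Michaelis-Menten light-response parameters (apparent quantum yield
#' `alpha`, umol CO2 per umol photon; reference GPP at light saturation of
#' 2000 umol m-2 s-1) per month May-September, for the drought year 2018,
#' the legacy year 2019 and the pooled remaining years.
#'
#' @return data.frame with `month`, `year_set`, `alpha`, `gpp_ref`.
#' @export
site_light_response <- function() {
  utils::read.csv(system.file("extdata", "dehoh_light_response.csv",
                              package = "fluxlegacy"))
}

#' Site-level drought and legacy summary statistics
#'
#' Computes, from the published budget and light-response tables, the
#' summary quantities that frame the legacy analysis:
#' \describe{
#'   \item{mean_annual_nep}{mean annual NEP over all years (gC m-2).}
#'   \item{pre_drought_mean_nep}{mean annual NEP of the pre-drought years.}
#'   \item{nep_reduction_legacy_pct}{relative NEP reduction of the legacy
#'     year versus the pre-drought mean (%).}
#'   \item{gs_elongation_days}{mean growing-season length of the drought
#'     and legacy years minus the mean of the other years (days).}
#'   \item{gs_precip_share_drought_pct}{growing-season share of annual
#'     precipitation in the drought year (%).}
#'   \item{gpp_ref_ratio_pct}{mid-summer (Jul-Aug) reference GPP of the
#'     drought year as a percentage of the non-drought years.}
#' }
#'
#' @param budgets table as from [site_annual_budgets()].
#' @param light table as from [site_light_response()].
#' @param drought_year,legacy_year,pre_drought_years year roles.
#' @return named list of the six statistics.
#' @export
site_summary_stats <- function(budgets = site_annual_budgets(),
                               light = site_light_response(),
                               drought_year = 2018, legacy_year = 2019,
                               pre_drought_years = 2015:2017) {
  fy <- budgets[budgets$period == "full", ]
  gs <- budgets[budgets$period == "growing_season", ]
  pre <- mean(fy$nep[fy$year %in% pre_drought_years])
  long_years <- c(drought_year, legacy_year)
  other <- setdiff(fy$year, long_years)
  midsummer <- light[light$month %in% 7:8, ]
  ref_drought <- sum(midsummer$gpp_ref[midsummer$year_set ==
                                         as.character(drought_year)])
  ref_other <- sum(midsummer$gpp_ref[midsummer$year_set == "others"])
  list(
    mean_annual_nep = mean(fy$nep),
    pre_drought_mean_nep = pre,
    nep_reduction_legacy_pct =
      100 * (1 - fy$nep[fy$year == legacy_year] / pre),
    gs_elongation_days =
      mean(gs$gs_length[gs$year %in% long_years]) -
      mean(gs$gs_length[gs$year %in% other]),
    gs_precip_share_drought_pct =
      100 * gs$prec[gs$year == drought_year] /
      fy$prec[fy$year == drought_year],
    gpp_ref_ratio_pct = 100 * ref_drought / ref_other
  )
}
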