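#' Configuration for the synthetic flux-tower generator
#'
#' Builds the parameter set that drives [simulate_daily_climate()],
#' [simulate_halfhourly()] and [simulate_gcc()]. Defaults emulate a temperate
#' mixed deciduous forest in the Central German lowlands (~52 N, 200 m a.s.l.,
#' mean annual temperature ~9 C, mean annual precipitation ~560 mm).
#'
#' All stochastic stages draw from sub-streams derived from `seed`, so the
#' weather stream can be held fixed while process noise, gaps or the legacy
#' mechanism are toggled.
#'
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param years integer vector of calendar years to simulate.
#' @param latitude site latitude in decimal degrees (|lat| < 66.5).
#' @param annual_precip_mean target mean annual precipitation (mm).
#' @param drought_years named list: one entry per drought year, each a list
#'   with `precip_mult` (multiplier on precipitation amounts), `temp_offset`
#'   (additive temperature anomaly, C) and optionally `months` (the months
#'   the event spans; default April-October, a summer drought). With the
#'   event confined to the warm season, the trailing 365-day water deficit
#'   peaks after the event and stays anomalous through the following
#'   spring/summer, which is what makes the next year a legacy candidate.
#' @param legacy_gain multiplicative GPP factor in (0, 1] reached when the
#'   lagged 365-day climatic water deficit is at or beyond
#'   `legacy_deficit_full`; 1 disables the legacy mechanism.
#' @param legacy_deficit_onset,legacy_deficit_full standardized 365-day
#'   water deficit (PET - P aggregated over the trailing year, expressed as
#'   a z-score against the simulation's non-drought climatology) at which
#'   the legacy GPP suppression starts ramping in and at which it saturates
#'   at `legacy_gain`.
#' @param legacy_lag days by which the deficit driver trails the suppression
#'   (carry-over time of the physiological damage); 0 couples the factor to
#'   the concurrent trailing-year deficit.
#' @param true_ustar_threshold friction velocity (m s-1) below which measured
#'   nighttime NEE is suppressed.
#' @param night_suppression_factor multiplier in (0, 1] applied to measured
#'   nighttime NEE when u* is below the threshold (1 = no suppression).
#' @param gap_fraction fraction of NEE records turned into gaps, in [0, 0.5).
#' @param noise_sd_nee standard deviation of additive Gaussian measurement
#'   noise on NEE (umol m-2 s-1).
#' @param lt_params Lloyd-Taylor ground truth: `rref` (umol m-2 s-1 at 15 C)
#'   and `e0` (K).
#' @param lr_params light-response ground truth: `alpha` (umol CO2 per umol
#'   photon) and `gpp_max` (umol m-2 s-1, hyperbola asymptote), plus the
#'   moisture-stress ramp `swc_wilt` and `swc_opt` (volumetric %).
#' @param pheno_params double-logistic ground truth: `baseline`, `amplitude`
#'   (Gcc units), spring/autumn inflection days `t1`, `t2` (DOY) and slopes
#'   `c1`, `c2` (per day).
#'
#' @return an object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, years = 2015:2016)
#' cfg$true_ustar_threshold
sim_config <- function(seed = 1L,
                       years = 2015:2020,
                       latitude = 52.08,
                       annual_precip_mean = 563,
                       drought_years = list(
                         "2018" = list(precip_mult = 0.40, temp_offset = 2.0,
                                       months = 4:12),
                         "2019" = list(precip_mult = 0.50, temp_offset = 0.5,
                                       months = 1:3)
                       ),
                       legacy_gain = 1,
                       legacy_deficit_onset = 1.8,
                       legacy_deficit_full = 2.4,
                       legacy_lag = 0,
                       true_ustar_threshold = 0.35,
                       night_suppression_factor = 0.5,
                       gap_fraction = 0.10,
                       noise_sd_nee = 1.5,
                       lt_params = list(rref = 2.5, e0 = 180),
                       lr_params = list(alpha = 0.05, gpp_max = 30,
                                        swc_wilt = 10, swc_opt = 20),
                       pheno_params = list(baseline = 0.32, amplitude = 0.10,
                                           t1 = 120, c1 = 0.15,
                                           t2 = 290, c2 = 0.10)) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L || anyNA(years))
    stop("`years` must be a nonempty vector of calendar years", call. = FALSE)
  if (abs(latitude) >= 66.5)
    stop("polar latitudes are not supported", call. = FALSE)
  if (annual_precip_mean < 0)
    stop("`annual_precip_mean` must be nonnegative", call. = FALSE)
  if (!(legacy_gain > 0 && legacy_gain <= 1))
    stop("`legacy_gain` must lie in (0, 1]", call. = FALSE)
  if (!(gap_fraction >= 0 && gap_fraction < 0.5))
    stop("`gap_fraction` must lie in [0, 0.5)", call. = FALSE)
  if (!(night_suppression_factor > 0 && night_suppression_factor <= 1))
    stop("`night_suppression_factor` must lie in (0, 1]", call. = FALSE)
  dy <- names(drought_years)
  if (length(drought_years) && is.null(dy))
    stop("`drought_years` must be a named list keyed by year", call. = FALSE)
  for (y in dy) {
    m <- drought_years[[y]]
    if (!is.null(m$precip_mult) && m$precip_mult < 0)
      stop("negative precipitation multiplier for year ", y, call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), years = years, latitude = latitude,
    annual_precip_mean = annual_precip_mean, drought_years = drought_years,
    legacy_gain = legacy_gain,
    legacy_deficit_onset = legacy_deficit_onset,
    legacy_deficit_full = legacy_deficit_full,
    legacy_lag = as.integer(legacy_lag),
    true_ustar_threshold = true_ustar_threshold,
    night_suppression_factor = night_suppression_factor,
    gap_fraction = gap_fraction, noise_sd_nee = noise_sd_nee,
    lt_params = lt_params, lr_params = lr_params,
    pheno_params = pheno_params
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  years:", paste(range(x$years), collapse = "-"),
      sprintf("(%d)", length(x$years)), "\n")
  cat("  latitude:", x$latitude, "deg; mean annual precip:",
      x$annual_precip_mean, "mm\n")
  cat("  drought years:",
      if (length(x$drought_years)) paste(names(x$drought_years), collapse = ", ")
      else "none", "\n")
  cat("  legacy gain:", x$legacy_gain,
      "| u* threshold:", x$true_ustar_threshold, "m s-1",
      "| gap fraction:", x$gap_fraction, "\n")
  invisible(x)
}

# Deterministic sub-stream seeds so the weather stream is unchanged when
# process noise, gaps or greenness noise are toggled.
.sub_seed <- function(cfg, stream) {
  offset <- switch(stream,
    climate = 101L, radiation = 202L, ustar = 303L,
    noise = 404L, gaps = 505L, gcc = 606L,
    stop("unknown stream: ", stream)
  )
  (cfg$seed %% 2000000L) * 1000L + offset
}

.days_in_year <- function(year) {
  as.integer(as.Date(sprintf("%d-12-31", year)) -
             as.Date(sprintf("%d-01-01", year))) + 1L
}
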