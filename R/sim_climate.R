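#' Simulate daily climate forcing
#'
#' Generates a daily weather series for the configured years: precipitation
#' from a two-state (wet/dry) occurrence chain with Gamma-distributed amounts,
#' and temperature as a seasonal sinusoid plus AR(1) anomalies. Years listed
#' in `cfg$drought_years` have their precipitation amounts multiplied and a
#' temperature offset added, which is how drought/heat years are injected.
#'
#' The occurrence chain uses P(wet | dry) = 0.33 and P(wet | wet) = 0.50
#' (stationary wet-day frequency ~0.40); the Gamma amount distribution has
#' shape 1.4 and its mean is calibrated so that the expected annual total
#' equals `cfg$annual_precip_mean`.
#'
#' @param cfg a [sim_config()] object.
#' @return a `data.frame` with columns `date`, `precip` (mm d-1), `tmin`,
#'   `tmax`, `tmean` (C) and `latitude` (degrees), one row per day.
#' @export
#' @examples
#' clim <- simulate_daily_climate(sim_config(seed = 1, years = 2015))
#' head(clim)
simulate_daily_climate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg, "climate"))

  # supports non-contiguous year lists
  date <- unlist(lapply(cfg$years, function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), 1)
  }))
  date <- as.Date(date, origin = "1970-01-01")
  n <- length(date)
  year <- as.integer(format(date, "%Y"))
  doy <- as.integer(format(date, "%j"))

  # --- precipitation occurrence: 2-state chain -------------------------------
  p01 <- 0.33; p11 <- 0.50
  pi_wet <- p01 / (1 + p01 - p11)
  u_occ <- stats::runif(n)
  wet <- logical(n)
  wet[1] <- u_occ[1] < pi_wet
  for (i in 2:n) wet[i] <- u_occ[i] < if (wet[i - 1]) p11 else p01

  shape <- 1.4
  mean_amt <- cfg$annual_precip_mean / (365.25 * pi_wet)
  amt <- stats::rgamma(n, shape = shape, scale = mean_amt / shape)
  precip <- ifelse(wet, amt, 0)

  # --- temperature: seasonal sinusoid + AR(1) anomaly ------------------------
  t_base <- 9.1 + 9.0 * cos(2 * pi * (doy - 200) / 365.25)
  innov <- stats::rnorm(n, sd = 1.5)
  anom <- as.numeric(stats::filter(innov, 0.8, method = "recursive"))
  tmean <- t_base + anom
  # diurnal range: wider on dry days, never negative
  rng <- pmax(2, 8 + 2 * stats::rnorm(n) - 2 * wet)

  # --- drought-year modifiers (default: the April-October season) -----------
  mo <- as.integer(format(date, "%m"))
  for (y in names(cfg$drought_years)) {
    m <- cfg$drought_years[[y]]
    months <- if (is.null(m$months)) 4:10 else m$months
    sel <- year == as.integer(y) & mo %in% months
    if (!any(sel)) next
    if (!is.null(m$precip_mult)) precip[sel] <- precip[sel] * m$precip_mult
    if (!is.null(m$temp_offset)) tmean[sel] <- tmean[sel] + m$temp_offset
  }

  data.frame(
    date = date,
    precip = precip,
    tmin = tmean - 0.45 * rng,
    tmax = tmean + 0.55 * rng,
    tmean = tmean,
    latitude = cfg$latitude
  )
}
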