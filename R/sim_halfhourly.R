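#' Simulate a half-hourly flux-tower record
#'
#' Expands a daily climate series into half-hourly meteorology and CO2 fluxes
#' with known ground truth. Incoming shortwave radiation is clear-sky
#' potential radiation (from latitude, day of year and hour) times a daily
#' cloudiness factor tied to precipitation; PPFD is 2.1 umol J-1 times SW_IN.
#' True ecosystem respiration follows the Lloyd-Taylor model of temperature;
#' true GPP is a rectangular hyperbola of PPFD modulated by a soil-moisture
#' stress ramp, a double-logistic phenology window and (optionally) a
#' drought-legacy suppression driven by the lagged 365-day climatic water
#' deficit (PET - P). Soil water content follows a single-layer bucket with
#' infiltration from precipitation, GPP-driven transpiration, drainage and
#' saturation excess.
#'
#' Measured NEE = true Reco - true GPP + Gaussian noise, and nighttime
#' records (SW_IN < 10 W m-2) with u* below `cfg$true_ustar_threshold` are
#' multiplied by `cfg$night_suppression_factor`, emulating the flux loss
#' under low turbulence that u* filtering must detect. Gaps (NA) are inserted
#' as random singles plus contiguous blocks totalling `cfg$gap_fraction` of
#' the record.
#'
#' @param cfg a [sim_config()] object.
#' @param climate daily climate table from [simulate_daily_climate()]; must
#'   cover every configured year.
#' @return a list of class `flux_sim` with elements
#'   \describe{
#'     \item{data}{half-hourly `data.frame` (`timestamp` = end of interval,
#'       local standard time; `NEE`, `H`, `LE`, `Rn`, `G`, `ustar`, `SW_IN`,
#'       `PPFD`, `TA`, `RH`, `VPD`, `Prec`, `SWC_50`).}
#'     \item{truth}{ground truth per half-hour: `gpp_true`, `reco_true`,
#'       `nee_true`, `suppressed`, `gap`, `legacy_factor`, water-balance
#'       components (`infil`, `transp`, `drain`, `runoff`, mm).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_halfhourly <- function(cfg, climate = simulate_daily_climate(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  cyears <- unique(as.integer(format(climate$date, "%Y")))
  if (!all(cfg$years %in% cyears))
    stop("`climate` does not cover all configured years", call. = FALSE)
  climate <- climate[as.integer(format(climate$date, "%Y")) %in% cfg$years, ]
  climate <- climate[order(climate$date), ]

  nd <- nrow(climate)
  n <- nd * 48L
  day_idx <- rep(seq_len(nd), each = 48L)
  hh <- rep(seq_len(48L), nd)                      # interval index within day
  hour_mid <- (hh - 0.5) * 0.5                     # midpoint hour of interval
  timestamp <- as.POSIXct(paste(climate$date[day_idx], "00:00:00"),
                          tz = "UTC") + hh * 1800
  doy <- as.integer(format(climate$date, "%j"))[day_idx]

  # --- radiation -------------------------------------------------------------
  lat_r <- cfg$latitude * pi / 180
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  hang <- pi / 12 * (hour_mid - 12)                # hour angle
  cosz <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(hang)
  sw_pot <- 1361 * 0.75 * pmax(cosz, 0)

  set.seed(.sub_seed(cfg, "radiation"))
  wet <- climate$precip > 0
  cloud <- ifelse(wet,
                  stats::runif(nd, 0.15, 0.55),
                  stats::runif(nd, 0.50, 1.00))
  sw_in <- sw_pot * cloud[day_idx]
  ppfd <- 2.1 * sw_in
  night <- sw_in < 10

  # --- temperature, humidity -------------------------------------------------
  rng <- (climate$tmax - climate$tmin)[day_idx]
  ta <- climate$tmean[day_idx] + 0.5 * rng * cos(2 * pi * (hour_mid - 14) / 24)
  es <- .magnus(ta)
  ea <- pmin(.magnus(climate$tmin[day_idx]), es)
  rh <- pmin(pmax(100 * ea / es, 5), 100)
  vpd <- es - ea

  # --- friction velocity -----------------------------------------------------
  set.seed(.sub_seed(cfg, "ustar"))
  ustar <- ifelse(night,
                  stats::rlnorm(n, log(0.25), 0.5),
                  stats::rlnorm(n, log(0.45), 0.4))

  # --- legacy factor from lagged 365-day water deficit -----------------------
  pet <- pet_hargreaves(climate)
  deficit <- .lagged_deficit(pet - climate$precip, 365L)
  lag <- if (is.null(cfg$legacy_lag)) 0L else cfg$legacy_lag
  deficit <- deficit[pmax(seq_along(deficit) - lag, 1L)]
  # standardize against a 30-year drought-free climatology from the same
  # weather generator, so the ramp marks anomalous dryness on a stable
  # baseline rather than the handful of observed normal years
  ref_cfg <- cfg
  ref_cfg$years <- 1971:2000
  ref_cfg$drought_years <- list()
  ref_clim <- simulate_daily_climate(ref_cfg)
  ref_def <- .lagged_deficit(pet_hargreaves(ref_clim) - ref_clim$precip,
                             365L)
  ref_def <- ref_def[-seq_len(365L)]
  z_def <- (deficit - mean(ref_def)) / stats::sd(ref_def)
  full_win <- seq_along(deficit) > 365L - lag
  z_def[!full_win] <- 0   # no drought history in the incomplete first year
  ramp <- (z_def - cfg$legacy_deficit_onset) /
    (cfg$legacy_deficit_full - cfg$legacy_deficit_onset)
  legacy_day <- 1 - (1 - cfg$legacy_gain) * pmin(pmax(ramp, 0), 1)

  # --- phenology window ------------------------------------------------------
  pp <- cfg$pheno_params
  pw <- 1 / (1 + exp(-pp$c1 * (doy - pp$t1))) +
        1 / (1 + exp( pp$c2 * (doy - pp$t2))) - 1
  pw <- pmax(pw, 0)

  # --- soil-moisture bucket + true fluxes (sequential) -----------------------
  lt <- cfg$lt_params; lr <- cfg$lr_params
  reco_true <- lloyd_taylor(ta, lt$rref, lt$e0)
  prec_hh <- climate$precip[day_idx] / 48          # uniform within day
  z_mm <- 500                                      # bucket depth, mm of soil
  sat <- 60; fc <- 40                              # volumetric %
  hyper <- (lr$alpha * ppfd * lr$gpp_max) / (lr$alpha * ppfd + lr$gpp_max)
  legacy_hh <- legacy_day[day_idx]

  swc <- numeric(n); gpp_true <- numeric(n)
  infil <- numeric(n); transp <- numeric(n)
  drain <- numeric(n); runoff <- numeric(n)
  store <- 30 / 100 * z_mm                         # initial storage, mm
  for (i in seq_len(n)) {
    s <- 100 * store / z_mm
    swc[i] <- s
    f_sw <- min(max((s - lr$swc_wilt) / (lr$swc_opt - lr$swc_wilt), 0), 1)
    g <- hyper[i] * f_sw * pw[i] * legacy_hh[i]
    gpp_true[i] <- g
    tr <- min(0.01 * g, max(store - lr$swc_wilt / 100 * z_mm, 0))
    dr <- 0.02 * max(store - fc / 100 * z_mm, 0)
    inf <- prec_hh[i]
    excess <- max(store + inf - tr - dr - sat / 100 * z_mm, 0)
    infil[i] <- inf; transp[i] <- tr; drain[i] <- dr; runoff[i] <- excess
    store <- store + inf - tr - dr - excess
  }

  nee_true <- reco_true - gpp_true

  # --- measurement layer -----------------------------------------------------
  set.seed(.sub_seed(cfg, "noise"))
  nee <- nee_true + stats::rnorm(n, sd = cfg$noise_sd_nee)
  suppressed <- night & ustar < cfg$true_ustar_threshold
  nee[suppressed] <- nee[suppressed] * cfg$night_suppression_factor

  gap <- .draw_gaps(n, cfg$gap_fraction, .sub_seed(cfg, "gaps"))
  nee[gap] <- NA_real_

  # --- energy fluxes (coarse but internally consistent) ----------------------
  rn <- 0.85 * sw_in - 35
  le <- transp * 2.45e6 / 1800                     # mm per 30 min -> W m-2
  g_soil <- 0.1 * rn
  h <- rn - le - g_soil

  data <- data.frame(
    timestamp = timestamp,
    NEE = nee, H = h, LE = le, Rn = rn, G = g_soil,
    ustar = ustar, SW_IN = sw_in, PPFD = ppfd,
    TA = ta, RH = rh, VPD = vpd, Prec = prec_hh, SWC_50 = swc
  )
  truth <- data.frame(
    timestamp = timestamp,
    gpp_true = gpp_true, reco_true = reco_true, nee_true = nee_true,
    suppressed = suppressed, gap = gap,
    legacy_factor = legacy_hh, pheno_window = pw,
    infil = infil, transp = transp, drain = drain, runoff = runoff
  )
  structure(list(data = data, truth = truth, config = cfg),
            class = "flux_sim")
}

#' @export
print.flux_sim <- function(x, ...) {
  cat("<flux_sim>", nrow(x$data), "half-hours,",
      length(x$config$years), "year(s);",
      sprintf("%.1f%% NEE missing\n", 100 * mean(is.na(x$data$NEE))))
  invisible(x)
}

#' Lloyd-Taylor respiration model
#'
#' `Reco(T) = Rref * exp(E0 * (1/(Tref - T0) - 1/(T - T0)))` with the
#' conventional constants Tref = 15 C and T0 = -46.02 C.
#'
#' @param ta air temperature (C).
#' @param rref respiration at the 15 C reference temperature (umol m-2 s-1).
#' @param e0 temperature-sensitivity parameter (K).
#' @param tref,t0 reference and zero-respiration temperatures (C).
#' @return respiration (umol m-2 s-1).
#' @export
lloyd_taylor <- function(ta, rref, e0, tref = 15, t0 = -46.02) {
  rref * exp(e0 * (1 / (tref - t0) - 1 / (ta - t0)))
}

# Magnus saturation vapour pressure (hPa) over water.
.magnus <- function(ta) 6.1078 * exp(17.08085 * ta / (234.175 + ta))

# Trailing 365-day sum of a daily series; the incomplete head is scaled up
# from the expanding partial sum so year 1 is usable.
.lagged_deficit <- function(x, k = 365L) {
  n <- length(x)
  cs <- cumsum(x)
  out <- numeric(n)
  idx <- seq_len(n)
  full <- idx >= k
  out[full] <- cs[idx[full]] - c(0, cs)[idx[full] - k + 1L]
  out[!full] <- cs[idx[!full]] * (k / idx[!full])
  out
}

# Exactly round(frac * n) gap indices: half in contiguous blocks, rest singles.
.draw_gaps <- function(n, frac, seed) {
  gap <- logical(n)
  n_gap <- round(frac * n)
  if (n_gap == 0) return(gap)
  set.seed(seed)
  target_block <- floor(n_gap / 2)
  filled <- 0L
  guard <- 0L
  while (filled < target_block && guard < 10000L) {
    guard <- guard + 1L
    len <- sample(8:48, 1L)
    len <- min(len, target_block - filled + 8L)
    start <- sample.int(n - len + 1L, 1L)
    span <- start:(start + len - 1L)
    fresh <- span[!gap[span]]
    gap[fresh] <- TRUE
    filled <- filled + length(fresh)
  }
  remaining <- n_gap - sum(gap)
  if (remaining > 0) {
    free <- which(!gap)
    gap[sample(free, min(remaining, length(free)))] <- TRUE
  } else if (remaining < 0) {
    on <- which(gap)
    gap[sample(on, -remaining)] <- FALSE
  }
  gap
}
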