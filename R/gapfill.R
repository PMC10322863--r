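#' Gap-filling by marginal distribution sampling (MDS)
#'
#' Fills gaps in a half-hourly series by averaging donor records measured
#' under similar meteorological conditions within an expanding time window,
#' following the look-up-table cascade that is standard for eddy-covariance
#' post-processing. Similarity margins default to SW_IN 50 W m-2, TA 2.5 C
#' and VPD 5.0 hPa.
#'
#' The cascade, in order, with the quality grade attached to each step:
#' \enumerate{
#'   \item donors matching all covariates, window +/- 7 days (grade A);
#'   \item all covariates, +/- 14 days (A);
#'   \item SW_IN only, +/- 7 days (B);
#'   \item mean diurnal course (same half-hour +/- 1 h), windows expanding
#'     +/- 0, 1, 2 days (B) then up to +/- 7 days (C);
#'   \item all covariates, windows widening in 7-day steps to +/- 70 d (C);
#'   \item SW_IN only, widening to +/- 70 d (C);
#'   \item mean diurnal course widening to +/- 210 d (C).
#' }
#' The filled value is the unweighted mean of the donors; its standard
#' deviation is reported as the fill uncertainty. When `counterparts = TRUE`
#' every observed value additionally receives a filled counterpart computed
#' the same way (with itself excluded), which supports cross-validation of
#' the filling.
#'
#' @param table half-hourly table on a strict 30-min grid with `timestamp`,
#'   the target column, and the covariate columns.
#' @param target name of the column to fill (default `"NEE"`).
#' @param margins named numeric vector of similarity half-widths for the
#'   covariates.
#' @param covariates covariate columns used by the full look-up steps; the
#'   first one plays the role of the radiation-only fallback.
#' @param counterparts also compute filled counterparts of observed values.
#' @param same_tod restrict look-up donors to the same time of day (+/- 1 h)
#'   in addition to the covariate margins; used for meteorological targets
#'   whose diurnal cycle the covariates cannot resolve (e.g. nighttime TA).
#' @return an object of class `gapfill_result`: `data` is the input with
#'   added columns `<target>_f` (filled series), `<target>_fqc` (0 observed,
#'   1 grade A, 2 grade B, 3 grade C), `<target>_fsd` (donor sd),
#'   `<target>_fwin` (window half-width, days), `<target>_fmeth` (method
#'   code) and, if requested, `<target>_fall` (counterpart for every row);
#'   `n_filled` and `n_unfilled` summarise the outcome.
#' @export
gapfill_mds <- function(table, target = "NEE",
                        margins = c(SW_IN = 50, TA = 2.5, VPD = 5.0),
                        covariates = c("SW_IN", "TA", "VPD"),
                        counterparts = FALSE, same_tod = FALSE) {
  .check_grid(table$timestamp)
  if (!target %in% names(table))
    stop("target column `", target, "` not found", call. = FALSE)
  covariates <- intersect(covariates, names(table))
  covariates <- covariates[!vapply(covariates, function(v)
    all(is.na(table[[v]])), logical(1))]
  if (length(covariates) == 0L)
    stop("no usable covariates present", call. = FALSE)

  y <- table[[target]]
  n <- length(y)
  covm <- as.matrix(table[covariates])
  marg <- margins[covariates]
  rad <- covariates[1]
  radv <- table[[rad]]
  rad_marg <- margins[[rad]]
  hod <- ((seq_len(n) - 1L) %% 48L)   # position within day on the strict grid
  hod_l <- if (same_tod) hod else NULL

  fill_one <- function(i) {
    # step 1-2: all covariates
    if (!anyNA(covm[i, ])) {
      for (w in c(7L, 14L)) {
        d <- .mds_lookup(i, y, covm, marg, w, n, hod = hod_l)
        if (!is.null(d)) return(c(d, grade = if (w <= 14) 1 else 3,
                                  win = w, meth = 1))
      }
    }
    # step 3: radiation only
    if (!is.na(radv[i])) {
      d <- .mds_lookup(i, y, covm[, rad, drop = FALSE],
                       stats::setNames(rad_marg, rad), 7L, n, hod = hod_l)
      if (!is.null(d)) return(c(d, grade = 2, win = 7, meth = 2))
    }
    # step 4: mean diurnal course, +/-0..7 days
    for (w in 0:7) {
      d <- .mds_diurnal(i, y, hod, w, n)
      if (!is.null(d)) return(c(d, grade = if (w <= 2) 2 else 3,
                                win = w, meth = 3))
    }
    # step 5-7: widening windows, grade C
    if (!anyNA(covm[i, ])) {
      for (w in seq(21L, 70L, 7L)) {
        d <- .mds_lookup(i, y, covm, marg, w, n, hod = hod_l)
        if (!is.null(d)) return(c(d, grade = 3, win = w, meth = 1))
      }
    }
    if (!is.na(radv[i])) {
      for (w in seq(14L, 70L, 7L)) {
        d <- .mds_lookup(i, y, covm[, rad, drop = FALSE],
                         stats::setNames(rad_marg, rad), w, n, hod = hod_l)
        if (!is.null(d)) return(c(d, grade = 3, win = w, meth = 2))
      }
    }
    for (w in seq(14L, 210L, 7L)) {
      d <- .mds_diurnal(i, y, hod, w, n)
      if (!is.null(d)) return(c(d, grade = 3, win = w, meth = 3))
    }
    NULL
  }

  filled <- y
  fqc <- ifelse(is.na(y), NA_integer_, 0L)
  fsd <- rep(NA_real_, n)
  fwin <- rep(NA_integer_, n)
  fmeth <- rep(NA_integer_, n)
  gaps <- which(is.na(y))
  n_unfilled <- 0L
  for (i in gaps) {
    d <- fill_one(i)
    if (is.null(d)) { n_unfilled <- n_unfilled + 1L; next }
    filled[i] <- d[["mean"]]
    fsd[i] <- d[["sd"]]
    fqc[i] <- as.integer(d[["grade"]])
    fwin[i] <- as.integer(d[["win"]])
    fmeth[i] <- as.integer(d[["meth"]])
  }
  if (n_unfilled > 0L)
    warning(n_unfilled, " gap(s) could not be filled at the maximum window",
            call. = FALSE)

  out <- table
  out[[paste0(target, "_f")]] <- filled
  out[[paste0(target, "_fqc")]] <- fqc
  out[[paste0(target, "_fsd")]] <- fsd
  out[[paste0(target, "_fwin")]] <- fwin
  out[[paste0(target, "_fmeth")]] <- fmeth
  if (counterparts) {
    fall <- filled
    for (i in which(!is.na(y))) {
      d <- fill_one(i)
      fall[i] <- if (is.null(d)) NA_real_ else d[["mean"]]
    }
    out[[paste0(target, "_fall")]] <- fall
  }
  structure(list(data = out, target = target,
                 n_filled = length(gaps) - n_unfilled,
                 n_unfilled = n_unfilled),
            class = "gapfill_result")
}

#' Fill gaps in a meteorological driver
#'
#' Runs the MDS cascade of [gapfill_mds()] with the covariate set reduced to
#' the remaining available drivers (e.g. for TA the lookup conditions on
#' SW_IN and VPD), and with look-up donors additionally restricted to the
#' same time of day, since radiation and humidity cannot resolve the
#' diurnal temperature course at night.
#'
#' @inheritParams gapfill_mds
#' @param target `"TA"` or `"VPD"`.
#' @return a `gapfill_result`.
#' @export
fill_met <- function(table, target = c("TA", "VPD")) {
  target <- match.arg(target)
  covs <- setdiff(c("SW_IN", "TA", "VPD"), target)
  gapfill_mds(table, target = target,
              margins = c(SW_IN = 50, TA = 2.5, VPD = 5.0),
              covariates = covs, same_tod = TRUE)
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result>", x$target, ":", x$n_filled, "filled,",
      x$n_unfilled, "unfilled\n")
  invisible(x)
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Saturation vapour pressure by the Magnus formula
#' (6.1078 hPa, 17.08085, 234.175 C); VPD = es(TA) * (1 - RH/100).
#'
#' @param ta air temperature (C).
#' @param rh relative humidity (%).
#' @return VPD in hPa.
#' @export
vpd_from_ta_rh <- function(ta, rh) .magnus(ta) * (1 - rh / 100)

.check_grid <- function(ts) {
  if (is.unsorted(ts, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  step <- unique(diff(as.numeric(ts)))
  if (length(step) != 1L || step != 1800)
    stop("timestamps must form a strict 30-minute grid", call. = FALSE)
  invisible(TRUE)
}

# donors within +/- win days matching every covariate within its margin
.mds_lookup <- function(i, y, covm, marg, win, n, min_donors = 1L,
                        hod = NULL) {
  lo <- max(1L, i - win * 48L); hi <- min(n, i + win * 48L)
  j <- lo:hi
  j <- j[j != i & !is.na(y[j])]
  if (!is.null(hod)) {
    dh <- (hod[j] - hod[i]) %% 48L
    j <- j[dh <= 2L | dh >= 46L]
  }
  if (!length(j)) return(NULL)
  ok <- rep(TRUE, length(j))
  for (v in colnames(covm)) {
    ok <- ok & !is.na(covm[j, v]) & abs(covm[j, v] - covm[i, v]) <= marg[[v]]
    if (!any(ok)) return(NULL)
  }
  d <- y[j[ok]]
  if (length(d) < min_donors) return(NULL)
  c(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
}

# same half-hour +/- 1 h within +/- win days
.mds_diurnal <- function(i, y, hod, win, n) {
  lo <- max(1L, i - win * 48L - 2L); hi <- min(n, i + win * 48L + 2L)
  j <- lo:hi
  dh <- (hod[j] - hod[i]) %% 48L
  j <- j[(dh <= 2L | dh >= 46L) & j != i & !is.na(y[j])]
  if (!length(j)) return(NULL)
  d <- y[j]
  c(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
}
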