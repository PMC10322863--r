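#' Friction-velocity threshold detection (moving point method)
#'
#' Nighttime NEE measured under weak turbulence is biased low; the moving
#' point method finds the u* value above which nighttime NEE no longer
#' increases with u*. Night records (SW_IN < 10 W m-2) are grouped by
#' season; within a season the data are split into 6 equal-count air
#' temperature classes, each sorted into 20 equal-count u* classes. The
#' threshold of a temperature class is the lower u* edge of the lowest class
#' whose mean NEE reaches at least 95% of the mean NEE of the following 10
#' classes, requiring that at least one lower class fails that criterion
#' (otherwise night NEE is independent of u* and no threshold exists). Temperature classes where |Pearson r(TA, u*)| > 0.4 are
#' discarded (temperature-turbulence confounding). The season threshold is
#' the median over retained temperature classes; the annual threshold is the
#' maximum over that year's seasons.
#'
#' Seasons are DJF/MAM/JJA/SON, with December assigned to the following
#' year's DJF. Seasons with fewer than 120 valid night records, or where no
#' u* class satisfies the plateau criterion, are skipped with a warning; if
#' every season is skipped the function fails.
#'
#' @param table a half-hourly flux table with columns `timestamp`, `NEE`,
#'   `ustar`, `SW_IN`, `TA`.
#' @return an object of class `ustar_result`: `seasons` (per-season
#'   thresholds, m s-1), `annual` (per-year maxima), and `threshold`, the
#'   median of the annual thresholds, used by downstream filtering.
#' @seealso [bootstrap_ustar()], [apply_ustar()]
#' @export
detect_ustar_threshold <- function(table) {
  night <- .night_rows(table)
  ok <- !is.na(night$NEE) & !is.na(night$ustar) & !is.na(night$TA)
  night <- night[ok, ]
  if (nrow(night) == 0L) stop("no valid night records", call. = FALSE)

  skey <- .season_key(night$timestamp)
  seasons <- split(night, skey)
  sthr <- vapply(names(seasons), function(s) {
    d <- seasons[[s]]
    if (nrow(d) < 120L) {
      warning("season ", s, " skipped: only ", nrow(d), " night records",
              call. = FALSE)
      return(NA_real_)
    }
    thr <- .season_threshold(d)
    if (is.na(thr))
      warning("season ", s, ": no u* class met the plateau criterion",
              call. = FALSE)
    thr
  }, numeric(1))

  if (all(is.na(sthr)))
    stop("u* threshold not found in any season", call. = FALSE)

  syear <- as.integer(sub("-.*", "", names(sthr)))
  annual <- tapply(sthr, syear, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  res <- list(
    seasons = data.frame(season = names(sthr), threshold = unname(sthr),
                         row.names = NULL),
    annual = data.frame(year = as.integer(names(annual)),
                        threshold = as.numeric(annual), row.names = NULL),
    threshold = stats::median(as.numeric(annual), na.rm = TRUE),
    boot = NULL, q05 = NA_real_, q50 = NA_real_, q95 = NA_real_
  )
  class(res) <- "ustar_result"
  res
}

#' Bootstrap distribution of the u* threshold
#'
#' Resamples whole nights with replacement (preserving within-night
#' correlation), re-runs [detect_ustar_threshold()] on each resample, and
#' reports the 5%, 50% and 95% quantiles of the threshold distribution.
#' Downstream processing conventionally uses the median threshold, with the
#' 5%/95% thresholds giving the uncertainty band of derived budgets.
#'
#' @inheritParams detect_ustar_threshold
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed for the resampling.
#' @return an `ustar_result` whose `boot` holds the resampled thresholds and
#'   `q05`/`q50`/`q95` their quantiles.
#' @export
bootstrap_ustar <- function(table, n_boot = 100L, seed = 1L) {
  if (n_boot < 2L) stop("`n_boot` must be at least 2", call. = FALSE)
  res <- detect_ustar_threshold(table)   # must succeed on the full table

  night <- .night_rows(table)
  night <- night[!is.na(night$NEE) & !is.na(night$ustar) & !is.na(night$TA), ]
  # a "night" = records from noon to noon, grouped by the date noon falls on
  nid <- as.Date(night$timestamp - 12 * 3600, tz = "UTC")
  ids <- unique(nid)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(lapply(take, function(d) which(nid == d)), use.names = FALSE)
    out <- tryCatch(
      suppressWarnings(detect_ustar_threshold(night[rows, ]))$threshold,
      error = function(e) NA_real_)
    out
  }, numeric(1))
  q <- stats::quantile(boot, c(0.05, 0.5, 0.95), na.rm = TRUE, names = FALSE)
  res$boot <- boot
  res$q05 <- q[1]; res$q50 <- q[2]; res$q95 <- q[3]
  res
}

#' Flag low-turbulence records by a u* threshold
#'
#' Sets nighttime NEE (SW_IN < 10 W m-2) to missing wherever u* falls below
#' the threshold. Daytime rows are untouched.
#'
#' @inheritParams detect_ustar_threshold
#' @param threshold friction-velocity threshold (m s-1, >= 0).
#' @return the table with filtered NEE; the number of newly missing records
#'   is attached as attribute `n_removed`.
#' @export
apply_ustar <- function(table, threshold) {
  if (is.na(threshold) || threshold < 0)
    stop("`threshold` must be a nonnegative number", call. = FALSE)
  night <- table$SW_IN < 10
  drop <- night & !is.na(table$NEE) & !is.na(table$ustar) &
    table$ustar < threshold
  table$NEE[drop] <- NA_real_
  attr(table, "n_removed") <- sum(drop)
  table
}

#' @export
print.ustar_result <- function(x, ...) {
  cat("<ustar_result> threshold:", signif(x$threshold, 3), "m s-1\n")
  if (!is.null(x$boot))
    cat(sprintf("  bootstrap (n=%d): q05 %.3f | q50 %.3f | q95 %.3f\n",
                length(x$boot), x$q05, x$q50, x$q95))
  invisible(x)
}

.night_rows <- function(table) {
  need <- c("timestamp", "NEE", "ustar", "SW_IN", "TA")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  table[!is.na(table$SW_IN) & table$SW_IN < 10, need]
}

# DJF/MAM/JJA/SON key; December belongs to the following year's DJF.
.season_key <- function(ts) {
  mo <- as.integer(format(ts, "%m"))
  yr <- as.integer(format(ts, "%Y"))
  yr[mo == 12L] <- yr[mo == 12L] + 1L
  season <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
              "JJA", "JJA", "SON", "SON", "SON", "DJF")[mo]
  sprintf("%d-%s", yr, season)
}

# equal-count classes via type-1 quantile breaks: assignment depends only
# on the value distribution, so duplicating every record (or scaling the
# fluxes) leaves class membership unchanged
.value_classes <- function(x, n_class) {
  br <- unique(stats::quantile(x, (0:n_class) / n_class, type = 1))
  cut(x, br, include.lowest = TRUE, labels = FALSE)
}

.season_threshold <- function(d, n_ta = 6L, n_u = 20L,
                              plateau = 0.95, r_max = 0.4) {
  ta_class <- .value_classes(d$TA, n_ta)
  thr <- rep(NA_real_, n_ta)
  for (k in seq_len(max(ta_class))) {
    dk <- d[ta_class == k, ]
    if (nrow(dk) < 2L * n_u) next
    r <- suppressWarnings(stats::cor(dk$TA, dk$ustar))
    if (!is.na(r) && abs(r) > r_max) next
    uclass <- .value_classes(dk$ustar, n_u)
    if (max(uclass) < n_u) next
    mean_nee <- tapply(dk$NEE, uclass, mean)
    min_u <- tapply(dk$ustar, uclass, min)
    # pass_j: class j already at >= 95% of the mean of the (up to) 10
    # following classes. Suppression shows up as a consecutive run of
    # failing classes below the plateau; isolated marginal failures arise
    # from within-class temperature variance alone. A threshold therefore
    # exists only where a run of >= 3 consecutive classes fails, and it is
    # the lower u* edge of the class right above the last such run. If no
    # run fails, night NEE is independent of u* and the TA class reports
    # no threshold.
    pass <- rep(NA, n_u - 1L)
    for (j in seq_len(n_u - 1L)) {
      ref <- mean(mean_nee[(j + 1):min(j + 10L, n_u)])
      pass[j] <- mean_nee[j] >= plateau * ref
    }
    runs <- rle(!pass)
    ends <- cumsum(runs$lengths)
    fail_runs <- which(runs$values & runs$lengths >= 3L)
    if (length(fail_runs)) {
      last_fail <- ends[max(fail_runs)]
      if (last_fail < n_u)
        thr[k] <- min_u[last_fail + 1L] # lower edge of the plateau class
    }
  }
  if (all(is.na(thr))) NA_real_ else stats::median(thr, na.rm = TRUE)
}
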