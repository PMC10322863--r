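#' Restricted-cubic-spline regression of daily GPP on its drivers
#'
#' Fits `g(GPP) = b0 + sum over predictors of [linear + spline terms]` with
#' identity link by ordinary least squares on the column-bound restricted
#' cubic spline bases of the predictors (shared knot count, knots at the
#' default quantiles of each predictor). The coefficient covariance is
#' `sigma^2 (X'X)^-1`; the Gaussian log-likelihood, AIC (with the parameter
#' count including the error variance) and adjusted R^2 are stored with the
#' fit. Comparing a light/water-only model (PPFD, SWC) against one that
#' additionally carries drought history (SPEI at 90 and 365 days) is the
#' legacy-detection device: a drought-history model that fits markedly
#' better indicates that concurrent conditions alone cannot explain
#' productivity.
#'
#' @param data data.frame of daily values: the response column plus one
#'   column per predictor, and a `date` column (used by per-year metrics).
#' @param response name of the response column (daily GPP, gC m-2 d-1).
#' @param predictors character vector of predictor column names.
#' @param k shared number of knots (3-5).
#' @param knots optional named list of knot vectors overriding placement.
#' @return an object of class `rcs_model`.
#' @export
rcs_fit <- function(data, response = "GPP",
                    predictors = c("PPFD", "SWC_50"), k = 4, knots = NULL) {
  keep <- stats::complete.cases(data[c(response, predictors)])
  d <- data[keep, , drop = FALSE]
  y <- d[[response]]
  n <- length(y)

  kn <- list()
  blocks <- list()
  index <- list()
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    kn[[p]] <- if (!is.null(knots[[p]])) knots[[p]] else place_knots(d[[p]], k)
    B <- rcs_basis(d[[p]], kn[[p]])
    colnames(B) <- paste(p, colnames(B), sep = ".")
    index[[p]] <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
  }
  p_tot <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p_tot) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p_tot]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p_tot)
  xtx_inv <- chol2inv(qr.R(qr_x))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  n_par <- p_tot + 1                      # coefficients + error variance
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  structure(list(
    response = response, predictors = predictors, k = k, knots = kn,
    beta = beta, vcov = vcov, sigma2 = sigma2, rss = rss,
    n = n, p = p_tot, n_par = n_par, index = index,
    logLik = ll, aic = 2 * n_par - 2 * ll,
    r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p_tot),
    X = X, y = y, fitted = fitted,
    data = d
  ), class = "rcs_model")
}

#' @export
print.rcs_model <- function(x, ...) {
  cat("<rcs_model>", x$response, "~",
      paste(x$predictors, collapse = " + "),
      sprintf("(k = %d knots)\n", x$k))
  cat(sprintf("  n = %d, AIC = %.1f, adj R2 = %.3f\n", x$n, x$aic, x$adj_r2))
  invisible(x)
}

#' Predict from a restricted-cubic-spline model
#'
#' @param object an `rcs_model`.
#' @param newdata data.frame with the predictor columns; defaults to the
#'   training data.
#' @param ... unused.
#' @return numeric predictions (linear in the tails beyond the boundary
#'   knots by construction).
#' @export
predict.rcs_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (p in object$predictors)
    X <- cbind(X, rcs_basis(newdata[[p]], object$knots[[p]]))
  drop(X %*% object$beta)
}

#' Select the number of knots by AIC
#'
#' Fits the model for each shared knot count k in 3-5 and returns the fit
#' with the lowest AIC; ties go to the smaller k.
#'
#' @inheritParams rcs_fit
#' @param ks candidate knot counts.
#' @return the selected `rcs_model`; the AIC per candidate is attached as
#'   attribute `aic_grid`.
#' @export
select_knots <- function(data, response = "GPP",
                         predictors = c("PPFD", "SWC_50"), ks = 3:5) {
  fits <- lapply(ks, function(k)
    rcs_fit(data, response, predictors, k = k))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- fits[[which.min(aics)]]        # which.min takes the first = smallest k
  attr(best, "aic_grid") <- stats::setNames(aics, ks)
  best
}

#' Wald chi-square feature importance
#'
#' For the coefficient subset S of one predictor (its linear and spline
#' columns), `chi2 = beta_S' Sigma_S^-1 beta_S`; the importance score is
#' chi2 minus its degrees of freedom (the expected chi2 under no effect).
#' The nonlinearity fraction is the ratio of the partial sum of squares of
#' the spline columns to that of all the predictor's columns, both obtained
#' by removal refits, i.e. how much of the predictor's explained variance
#' needs the curved part of the spline.
#'
#' @param model an `rcs_model`.
#' @param predictor one of the model's predictors.
#' @return an object of class `importance_result`: `predictor`, `chi2`,
#'   `df`, `importance`, `nonlinearity`.
#' @export
feature_importance <- function(model, predictor) {
  if (!predictor %in% model$predictors)
    stop("`", predictor, "` is not in the model", call. = FALSE)
  S <- model$index[[predictor]]
  bS <- model$beta[S]
  VS <- model$vcov[S, S, drop = FALSE]
  VSi <- tryCatch(solve(VS), error = function(e)
    stop("singular covariance block for ", predictor, call. = FALSE))
  chi2 <- drop(t(bS) %*% VSi %*% bS)
  df <- length(S)

  rss_drop <- function(cols) {
    Xr <- model$X[, -cols, drop = FALSE]
    sum(qr.resid(qr(Xr), model$y)^2)
  }
  pss_all <- rss_drop(S) - model$rss
  spline_cols <- S[-1]                      # first column of the block is linear
  nl <- if (length(spline_cols)) {
    pss_spline <- rss_drop(spline_cols) - model$rss
    min(max(pss_spline / pss_all, 0), 1)
  } else 0
  structure(list(predictor = predictor, chi2 = chi2, df = df,
                 importance = chi2 - df, nonlinearity = nl),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf(
    "<importance> %s: chi2 %.1f (df %d) -> importance %.1f | nonlinearity %.2f\n",
    x$predictor, x$chi2, x$df, x$importance, x$nonlinearity))
  invisible(x)
}

#' Bivariate partial dependence surface
#'
#' Model prediction over a grid of two predictors, averaged over the
#' empirical joint distribution of the remaining predictors. Since the
#' model is additive across predictors, the surface is the sum of the two
#' predictors' contributions plus a constant. Grid points beyond the data
#' range are flagged (the spline is linear there).
#'
#' @param model an `rcs_model`.
#' @param pair character vector of two predictors in the model.
#' @param grid_sizes integer vector of grid sizes (recycled to length 2).
#' @return data.frame with the two grid coordinates, `pd` (surface value)
#'   and `extrapolated`.
#' @export
partial_dependence <- function(model, pair, grid_sizes = c(25, 25)) {
  stopifnot(length(pair) == 2, all(pair %in% model$predictors))
  grid_sizes <- rep_len(grid_sizes, 2)
  gx <- lapply(1:2, function(i) {
    v <- model$data[[pair[i]]]
    seq(min(v, na.rm = TRUE), max(v, na.rm = TRUE),
        length.out = grid_sizes[i])
  })
  contrib <- function(p, values) {
    B <- rcs_basis(values, model$knots[[p]])
    drop(B %*% model$beta[model$index[[p]]])
  }
  # constant part: intercept + mean contribution of the other predictors
  others <- setdiff(model$predictors, pair)
  const <- model$beta[[1]] +
    sum(vapply(others, function(p)
      mean(contrib(p, model$data[[p]])), numeric(1)))
  c1 <- contrib(pair[1], gx[[1]])
  c2 <- contrib(pair[2], gx[[2]])
  g <- expand.grid(x1 = gx[[1]], x2 = gx[[2]])
  names(g) <- pair
  g$pd <- const + as.vector(outer(c1, c2, "+"))
  rng <- lapply(pair, function(p) range(model$data[[p]], na.rm = TRUE))
  g$extrapolated <- g[[pair[1]]] < rng[[1]][1] | g[[pair[1]]] > rng[[1]][2] |
    g[[pair[2]]] < rng[[2]][1] | g[[pair[2]]] > rng[[2]][2]
  g
}

#' Per-year prediction error metrics
#'
#' For each calendar year with observations: RMSE; the mean percentage
#' error `MPE = 100 mean((obs - pred)/obs)` over days with obs at or above
#' a floor (default 0.5 gC m-2 d-1, avoiding winter near-zero
#' denominators; negative MPE = overestimation); and the within-year
#' adjusted R^2 of the global model's predictions.
#'
#' @param model an `rcs_model` fitted on data carrying a `date` column.
#' @param mpe_floor minimum observed value entering the MPE mean.
#' @param min_days years with fewer qualifying days are skipped.
#' @return data.frame (`year`, `n`, `rmse`, `mpe`, `adj_r2`).
#' @export
yearly_metrics <- function(model, mpe_floor = 0.5, min_days = 30L) {
  d <- model$data
  if (!"date" %in% names(d))
    stop("model data carries no `date` column", call. = FALSE)
  obs <- model$y
  pred <- model$fitted
  yr <- as.integer(format(d$date, "%Y"))
  out <- lapply(sort(unique(yr)), function(y) {
    i <- which(yr == y)
    qual <- i[obs[i] >= mpe_floor]
    if (length(qual) < min_days) return(NULL)
    res <- obs[i] - pred[i]
    r2 <- 1 - sum(res^2) / sum((obs[i] - mean(obs[i]))^2)
    ny <- length(i)
    data.frame(
      year = y, n = ny,
      rmse = sqrt(mean(res^2)),
      mpe = 100 * mean((obs[qual] - pred[qual]) / obs[qual]),
      adj_r2 = 1 - (1 - r2) * (ny - 1) / (ny - model$p)
    )
  })
  do.call(rbind, out)
}

#' Compare a concurrent-drivers model against a drought-history model
#'
#' Reports the AIC and adjusted-R^2 differences, per-year MPE of both
#' models, and the relative reduction of |MPE| in designated legacy years —
#' the quantity that flags a drought legacy: a year whose productivity the
#' concurrent-drivers model overestimates badly while the drought-history
#' model does not.
#'
#' @param simple,full two `rcs_model` fits on the same response rows.
#' @param legacy_years integer years suspected of carrying legacy effects.
#' @return object of class `model_comparison`: `delta_aic`
#'   (full - simple; negative favours the full model), `delta_adj_r2`,
#'   `years` (per-year MPE of both models and their difference), and
#'   `legacy_mpe_reduction` (named, relative |MPE| reduction per legacy
#'   year).
#' @export
compare_models <- function(simple, full, legacy_years = integer()) {
  if (simple$n != full$n || !isTRUE(all.equal(simple$y, full$y)))
    stop("models were not fitted on the same response rows", call. = FALSE)
  ys <- yearly_metrics(simple)
  yf <- yearly_metrics(full)
  years <- merge(ys[c("year", "rmse", "mpe", "adj_r2")],
                 yf[c("year", "rmse", "mpe", "adj_r2")],
                 by = "year", suffixes = c("_simple", "_full"))
  years$delta_mpe <- years$mpe_full - years$mpe_simple
  red <- vapply(legacy_years, function(y) {
    r <- years[years$year == y, ]
    if (nrow(r) == 0 || abs(r$mpe_simple) < 1e-12) return(NA_real_)
    (abs(r$mpe_simple) - abs(r$mpe_full)) / abs(r$mpe_simple)
  }, numeric(1))
  structure(list(
    delta_aic = full$aic - simple$aic,
    delta_adj_r2 = full$adj_r2 - simple$adj_r2,
    aic = c(simple = simple$aic, full = full$aic),
    adj_r2 = c(simple = simple$adj_r2, full = full$adj_r2),
    years = years,
    legacy_mpe_reduction = stats::setNames(red, legacy_years)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> dAIC = %.1f, d adj R2 = %+.3f\n",
              x$delta_aic, x$delta_adj_r2))
  print(x$years, row.names = FALSE)
  if (length(x$legacy_mpe_reduction))
    cat("legacy-year |MPE| reduction:",
        paste(sprintf("%s: %.0f%%", names(x$legacy_mpe_reduction),
                      100 * x$legacy_mpe_reduction), collapse = ", "), "\n")
  invisible(x)
}
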