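#' Knot placement for restricted cubic splines
#'
#' Places 3-5 knots at the canonical default quantiles: k = 3 at
#' (0.10, 0.50, 0.90), k = 4 at (0.05, 0.35, 0.65, 0.95), k = 5 at
#' (0.05, 0.275, 0.50, 0.725, 0.95). Ties are broken by nudging to the
#' nearest distinct data values so the knots are strictly increasing.
#'
#' @param x numeric predictor values (needs >= 5k distinct values).
#' @param k number of knots, 3-5.
#' @return strictly increasing numeric vector of length `k`.
#' @export
place_knots <- function(x, k) {
  if (!k %in% 3:5) stop("`k` must be 3, 4 or 5", call. = FALSE)
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  if (length(ux) < 5 * k)
    stop("need at least ", 5 * k, " distinct values for k = ", k,
         call. = FALSE)
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  kn <- unname(stats::quantile(x, probs, type = 7))
  if (any(duplicated(kn))) {
    used <- c()
    for (i in seq_along(kn)) {
      cand <- ux[!ux %in% used]
      kn[i] <- cand[which.min(abs(cand - kn[i]))]
      used <- c(used, kn[i])
    }
    kn <- sort(kn)
  }
  if (any(diff(kn) <= 0))
    stop("could not place strictly increasing knots", call. = FALSE)
  kn
}

#' Restricted cubic spline basis
#'
#' Truncated-power construction of the natural (restricted) cubic spline
#' basis: for k knots the basis has k - 1 columns — the identity (linear)
#' column plus k - 2 nonlinear columns — with the two tail constraints
#' making the fitted function linear below the first and above the last
#' knot. Nonlinear columns are scaled by the conventional
#' `(k_max - k_min)^2` normalisation so all columns share the predictor's
#' units.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knots from [place_knots()].
#' @return numeric matrix with `length(knots) - 1` columns; column 1 is `x`
#'   itself, the rest are the restricted cubic terms.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing",
                                  call. = FALSE)
  norm <- (knots[k] - knots[1])^2
  p3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <-
      (p3(x - knots[j]) -
         p3(x - knots[k - 1]) * (knots[k] - knots[j]) /
           (knots[k] - knots[k - 1]) +
         p3(x - knots[k]) * (knots[k - 1] - knots[j]) /
           (knots[k] - knots[k - 1])) / norm
  }
  colnames(out) <- c("lin", paste0("ncs", seq_len(k - 2)))
  out
}
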