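#' Simulate a daily canopy-greenness (Gcc) series
#'
#' Generates daily green chromatic coordinate values from the configured
#' double-logistic phenology plus Gaussian noise, with an injectable fraction
#' of low-illumination outliers (values forced below 0.2) and positive
#' spikes, mimicking the artefacts that the phenology filters must remove.
#'
#' @param cfg a [sim_config()] object (uses `pheno_params` and the `gcc`
#'   noise sub-stream).
#' @param noise_sd standard deviation of additive Gaussian noise (Gcc units).
#' @param frac_low fraction of days replaced by low-illumination values
#'   (uniform on 0.05-0.19).
#' @param frac_spike fraction of days with a positive spike added.
#' @param spike_size spike magnitude (Gcc units).
#' @return a `data.frame` with `date`, `gcc`, the clean curve `gcc_true`,
#'   and logical columns `is_low`, `is_spike` labelling injected artefacts.
#' @export
#' @examples
#' g <- simulate_gcc(sim_config(seed = 1, years = 2016), noise_sd = 0)
#' range(g$gcc_true)
simulate_gcc <- function(cfg, noise_sd = 0.005, frac_low = 0.03,
                         frac_spike = 0.02, spike_size = 0.1) {
  stopifnot(inherits(cfg, "sim_config"))
  pp <- cfg$pheno_params
  if (pp$t1 < 1 || pp$t2 > 366 || pp$t1 >= pp$t2)
    stop("phenology inflection dates must satisfy 1 <= t1 < t2 <= 366",
         call. = FALSE)
  date <- unlist(lapply(cfg$years, function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), 1)
  }))
  date <- as.Date(date, origin = "1970-01-01")
  doy <- as.integer(format(date, "%j"))
  n <- length(date)

  gcc_true <- double_logistic(doy, pp$baseline, pp$amplitude,
                              pp$t1, pp$c1, pp$t2, pp$c2)
  set.seed(.sub_seed(cfg, "gcc"))
  gcc <- gcc_true + stats::rnorm(n, sd = noise_sd)

  is_low <- is_spike <- logical(n)
  n_low <- round(frac_low * n)
  n_spike <- round(frac_spike * n)
  pool <- sample.int(n, n_low + n_spike)
  if (n_low > 0) {
    i <- pool[seq_len(n_low)]
    gcc[i] <- stats::runif(n_low, 0.05, 0.19)
    is_low[i] <- TRUE
  }
  if (n_spike > 0) {
    i <- pool[n_low + seq_len(n_spike)]
    gcc[i] <- gcc[i] + spike_size
    is_spike[i] <- TRUE
  }
  data.frame(date = date, gcc = gcc, gcc_true = gcc_true,
             is_low = is_low, is_spike = is_spike)
}

#' Double-logistic greenness curve
#'
#' `g(t) = b + a * (1/(1 + exp(-c1 (t - t1))) + 1/(1 + exp(c2 (t - t2))) - 1)`:
#' baseline `b`, seasonal amplitude `a`, spring and autumn inflection days
#' `t1 < t2` with slopes `c1`, `c2 > 0`.
#'
#' @param t day of year (may be fractional).
#' @param b,a baseline and amplitude (Gcc units).
#' @param t1,c1 spring inflection (DOY) and slope (d-1).
#' @param t2,c2 autumn inflection (DOY) and slope (d-1).
#' @return curve values at `t`.
#' @export
double_logistic <- function(t, b, a, t1, c1, t2, c2) {
  b + a * (1 / (1 + exp(-c1 * (t - t1))) + 1 / (1 + exp(c2 * (t - t2))) - 1)
}
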