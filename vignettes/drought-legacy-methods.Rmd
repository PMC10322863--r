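---
title: "Detecting drought legacy effects in eddy-covariance carbon fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drought legacy effects in eddy-covariance carbon fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fluxlegacy` implements the full analysis chain used to ask whether a
forest's carbon uptake in the year *after* an extreme drought can be
explained by that year's weather alone — and, when it cannot, to quantify
the unexplained part as a drought *legacy effect*. The chain runs from
half-hourly eddy-covariance post-processing (u* filtering, gap-filling,
flux partitioning) through a multi-scale daily drought index and
greenness-based phenology to a spline-regression model comparison. A
synthetic flux-tower generator with known ground truth stands in for the
raw tower record, so every stage is testable end to end.

```{r, eval = FALSE}
library(fluxlegacy)
cfg <- sim_config(seed = 1, years = 2015:2020, legacy_gain = 0.7)
res <- run_pipeline(cfg, legacy_years = 2019)
res$comparison
```

## The synthetic site

The generator emulates a temperate mixed deciduous forest in the Central
German lowlands (52 N, ~200 m a.s.l., mean annual temperature ~9 C, mean
annual precipitation 563 mm).

**Daily climate.** Precipitation occurrence follows a two-state chain
(P(wet|dry) = 0.33, P(wet|wet) = 0.50) with Gamma-distributed amounts
(shape 1.4) whose mean is calibrated to the configured annual total.
These settings give an interannual coefficient of variation of roughly
8–10%, at the lower end of what temperate lowland sites show; the choice
keeps a designed drought event statistically separable from weather noise
in a six-year record, which is the record length the analysis targets.
Temperature is a seasonal sinusoid (amplitude 9 C, peak DOY 200) plus
AR(1) anomalies.

**Drought years.** A drought is a set of months with a precipitation
multiplier and a temperature offset. The default configuration emulates
the shape of the 2018–2019 Central European event: April–December 2018 at
40% of normal precipitation and +2 C, followed by a dry January–March
2019 (50%). The seasonal timing matters: because the event is
concentrated in the warm season and the following winter, the *trailing
365-day climatic water balance* peaks after the drought summer and stays
extreme through the whole 2019 growing season, while the 2019 growing
season itself receives near-normal rain. That combination — anomalous
annual-scale deficit, unremarkable concurrent weather — is precisely what
defines a legacy candidate year, and it is why a model fed only
concurrent light and soil moisture fails there.

**Fluxes.** Shortwave radiation is clear-sky potential radiation (solar
geometry from latitude, day of year, hour; clear-sky transmittance 0.75)
times a daily cloudiness factor tied to rain occurrence; PPFD is fixed at
2.1 umol J-1 of shortwave — a standard approximation. True ecosystem
respiration follows the Lloyd–Taylor model (Rref = 2.5 umol m-2 s-1,
E0 = 180 K). True GPP is a rectangular hyperbola of PPFD
(alpha = 0.05, asymptote 30 umol m-2 s-1) modulated by (i) a soil-moisture
stress ramp between 10 and 20 vol%, (ii) a double-logistic phenology
window, and (iii) the legacy factor described below. Soil water content
follows a single-layer bucket (500 mm of soil, saturation 60 vol%, field
capacity 40 vol%) with infiltration, GPP-proportional transpiration,
drainage and saturation excess; the budget closes exactly at every step.

**Measurement layer.** Measured NEE adds Gaussian noise
(sd 1.5 umol m-2 s-1) and, for night records (SW_IN < 10 W m-2) with u*
below 0.35 m s-1, multiplies the flux by 0.5 — the low-turbulence
suppression that u* filtering must detect. Ten percent of NEE records
become gaps (half contiguous blocks of 4–24 h, half singles).
Weather, turbulence, noise, gap and greenness randomness draw from
separate sub-streams of the seed, so weather can be held fixed while the
legacy mechanism is toggled.

**The legacy mechanism.** The ecophysiological literature lists mechanisms
(hydraulic damage, carbohydrate depletion, delayed phenology) but
quantifies none, so the generator uses the simplest mechanism the model
stage can detect: a multiplicative GPP factor that ramps linearly with
the standardized trailing-365-day water deficit (PET − P). The deficit is
standardized against a 30-year drought-free climatology simulated by the
same weather generator (fixed internal years 1971–2000), so the ramp
thresholds are in climatological z-scores: suppression starts at z = 1.8
and saturates at z = 2.4, where GPP is multiplied by `legacy_gain`
(1 disables the mechanism entirely). With the default drought, the
z-score exceeds the saturation point throughout the post-drought growing
season and returns below onset during the second year after the event.

## u* threshold detection

Night records are grouped into seasons (DJF/MAM/JJA/SON, December
assigned forward), split into 6 equal-count temperature classes, and each
class into 20 equal-count u* classes. Classes are formed by type-1
quantile breaks on the values, which makes the detection invariant to
duplicating records or rescaling the fluxes. A temperature class is
discarded when |r(TA, u*)| > 0.4.

The plateau criterion asks whether a u* class already reaches 95% of the
mean NEE of the (up to) ten classes above it. Under the generator's
binary suppression the flux profile is flat below the threshold and flat
above it, so the lowest class trivially satisfies the ratio against its
suppressed neighbours; the criterion is therefore anchored on evidence of
suppression: a threshold exists only where a run of at least three
consecutive classes *fails* the criterion, and the threshold is the lower
u* edge of the class just above the last failing run. When no run fails,
nighttime NEE is independent of u* and the season reports "not found" —
no spurious thresholds on unsuppressed data. Bootstrap uncertainty
resamples whole nights (noon-to-noon) with replacement, 100 draws by
default; downstream budgets use the median threshold with the 5% and 95%
thresholds as the uncertainty band.

## Gap-filling

Marginal distribution sampling fills each gap with the mean of donor
records measured under similar conditions (SW_IN within 50 W m-2, TA
within 2.5 C, VPD within 5 hPa) in an expanding window: all covariates at
±7 then ±14 days (grade A), radiation only at ±7 days (grade B), the
mean diurnal course at the same half-hour ±1 h over ±0–2 days (B) and
±3–7 days (C), then all three routes with windows widening in 7-day steps
(C) out to ±210 days. The donor standard deviation is kept as the fill
uncertainty. Filling is idempotent, and the deletion test (removing 5% of
observed values) recovers the withheld data with RMSE below 1.5 times the
measurement noise. For meteorological targets (TA, VPD) the covariate set
reduces to the remaining drivers and look-up donors are additionally
restricted to the same time of day, because radiation and humidity cannot
resolve the diurnal temperature course at night. When VPD is absent it is
derived from TA and RH with the Magnus saturation formula (6.1078 hPa,
17.08085, 234.175 C).

## Flux partitioning (nighttime method)

Nighttime NEE is treated as respiration. The temperature sensitivity E0
of the Lloyd–Taylor model (Tref = 15 C, T0 = −46.02 C) is fitted in
15-day windows stepped by 5 days; windows are kept when they hold at
least 6 records spanning 5 C of temperature with E0 in [30, 450] K and a
relative standard error under 50%. The site E0 is the inverse-variance
weighted mean of the retained windows — windows with precise estimates
dominate, which keeps the estimator within a few Kelvin of truth under
realistic noise where a "best three windows" average scatters several
times wider. The reference respiration Rref(t) is then re-estimated in
7-day windows stepped by 4 days (regression through the origin on the
exponential temperature term) and interpolated to every half-hour.
Reco extends to all half-hours via the fitted model; GPP = Reco − NEE
without clipping (negative values are flagged), so NEE + GPP − Reco = 0
holds exactly everywhere. Monthly Michaelis–Menten light-response fits
(GPP = alpha PPFD gpp_max / (alpha PPFD + gpp_max)) summarize seasonal
carbon-uptake efficiency; the reference GPP is the curve evaluated at
PPFD = 2000 umol m-2 s-1. The daytime partitioning variant with a
VPD-modified light response is a documented extension point, not
implemented.

## Drought index

The daily SPEI standardizes the climatic water balance D_k = sum over k
days of (P − PET). PET uses Hargreaves
(0.0023 (Ra/2.45) (tmean + 17.8) sqrt(tmax − tmin)) with analytic
extraterrestrial radiation — a deliberate temperature-only choice for
daily climate records without radiation or humidity. For each aggregation
scale and calendar day, D_k pools the reference years within a ±15-day
window (Feb 29 with Feb 28), a three-parameter log-logistic distribution
is fitted by unbiased probability-weighted moments, and
SPEI = qnorm(F(D_k)) with F clamped to [0.0005, 0.9995], i.e.
|SPEI| ≤ 3.29. The PWM solution requires positive skew; daily
water-balance pools are usually left-skewed (the dry tail is long), in
which case the mirrored sample is fitted and the distribution flagged as
reflected — the standardization stays within the log-logistic family in
both orientations. Categories follow the usual thresholds: ≤ −1 moderate,
≤ −1.5 severe, ≤ −2 extreme, the last corresponding to a cumulative
probability of about 2.3%. The default scale grid spans 5–365 days.
Because a six-year record would absorb its own drought into the reference
distribution, `run_pipeline()` standardizes against a 30-year
drought-free climatology simulated by the same weather generator — the
role a long gridded climatology plays for real sites.

## Phenology

Gcc = G/(R+G+B) per image; the daily value is the 90th percentile of the
within-day values, which suppresses illumination variance. Filters drop
values below 0.2 (low illumination), points more than 3 scaled median
absolute deviations from a 15-day running median (the noise scale is
estimated from the MAD of first differences, which is robust to spikes
and insensitive to the seasonal signal), and days whose total brightness
deviates more than 50% from its 15-day running median. The filtered
series is fitted with the double logistic
g(t) = b + a (1/(1+e^{−c1(t−t1)}) + 1/(1+e^{c2(t−t2)}) − 1) by
multi-start nonlinear least squares (tolerance 1e-8). Transition dates
come from the curvature change rate dκ/dt of the fit, evaluated
analytically on a 0.1-day grid: season start is the first local maximum
on the rising limb (before t1 + 3/c1), season end the last local minimum
on the falling limb — the two extrema bracketing the full canopy cycle;
alternative conventions would select inner extrema (greenup/maturity)
instead. Uncertainty comes from 100 refits to the fitted curve plus
resampled residuals.

## Fingerprint correlations

Daily fluxes are z-transformed per calendar day across years; cells of
the fingerprint correlate the z-series with SPEI at each aggregation
scale over a 5-day DOY window pooled across years (about 5 x n_years
pairs per cell, Pearson, cells with fewer than 10 pairs dropped), for
growing-season days 110–300. Window summaries pool all pairs in a DOY x
scale rectangle and fit OLS z ~ SPEI; with both axes standardized the
slope approximates the window-mean correlation. The four default
rectangles are short (30–90 d) and long (300–365 d) scales in May
(DOY 121–151) and August (DOY 213–243).

## The legacy model

Daily GPP is regressed on restricted cubic splines of the predictors:
the *simple* model uses PPFD and SWC_50 (the photosynthesis equation's
light and water terms), the *full* model adds SPEI_90 and SPEI_365.
Knots sit at the conventional default quantiles (3 knots: 0.10/0.50/0.90;
4: 0.05/0.35/0.65/0.95; 5: 0.05/0.275/0.50/0.725/0.95), shared knot
count selected by AIC over 3–5 (ties to fewer knots). The basis is the
truncated-power natural-spline construction normalized by
(k_max − k_min)^2, linear beyond the boundary knots by construction.
Fitting is ordinary least squares (identity link); AIC counts all
coefficients plus the error variance and keeps the Gaussian constant, so
absolute AIC values are comparable across the package's own models.

Feature importance is the Wald statistic chi2 = beta_S' Sigma_S^-1 beta_S
over a predictor's coefficient block, minus its degrees of freedom (the
null expectation); it equals df times the nested-model F statistic, which
the tests verify to 1e-6. The nonlinearity fraction is the ratio of the
spline block's partial sum of squares to the whole predictor's, both by
removal refits. Per-year metrics are RMSE, adjusted R^2 of the global
fit within the year, and the mean percentage error
MPE = 100 mean((obs − pred)/obs) over days with observed GPP of at least
0.5 gC m-2 d-1 — the floor avoids near-zero winter denominators;
negative MPE means the model overestimates productivity. MPE is averaged
over all qualifying days of the year rather than growing-season days
only, so winter days with modest uptake also enter.

A legacy effect shows up as a year where the simple model's MPE is
strongly negative (productivity overestimated given the weather) while
the full model's is not. In the 20-seed experiment with `legacy_gain`
0.7, the full model's AIC is lower in every seed and the 2019 |MPE| is
cut by at least 40% relative in the majority, with median MPE moving from
about −29% to −11% — the desk-scale analogue of the published full-data
contrast.

## Budgets

Half-hourly carbon fluxes integrate with 1800 s x 12.011 ug umol-1
(molar mass of carbon, matching budgets in gC m-2); NEP = −NEE, positive
for uptake. Days missing any filled NEE are flagged and excluded from
sums. Period budgets cover years, months and greenness-derived growing
seasons (inclusive SOS–EOS); u*-threshold uncertainty propagates by
re-running filter, fill and partition at the bootstrap 5%/50%/95%
thresholds. Meteorological averages carry the standard error of the mean
of daily values.

## Problem sizes and limitations

The test-suite and acceptance runs use one to six simulated years per
scenario, 20 replicate seeds for stochastic checks, 100 bootstrap or
refit draws, and a 30-year reference climatology — sizes chosen so the
whole suite exercises every stage at full fidelity on a single CPU.

What the generator does not emulate bounds what passing tests show about
real data: advection and storage fluxes, energy-balance non-closure,
instrument drift and spectral losses, multi-layer soil moisture, species
composition, and any legacy mechanism other than a deterministic function
of the lagged water deficit. The u* detection rule is tuned to recover
step-like suppression; real sites show graded suppression, for which the
rule reduces to the canonical moving-point behaviour. The six-year
synthetic record also shares the real study's central caveat: one site,
one event, no replication of the drought itself.
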