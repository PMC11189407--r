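---
title: "Modelling temperature effects on the sex ratio at birth with distributed-lag additive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature effects on the sex ratio at birth with distributed-lag additive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrlag)
```

## The scientific problem

The secondary sex ratio (SSR) — the ratio of live-born boys to girls —
hovers around 105–107 boys per 100 girls, but it responds to environmental
stress. Ambient temperature around the time of conception is one candidate
stressor: temperature affects gametogenesis, implantation, and the
differential survival of male foetuses, so a month-resolved birth register
paired with a station temperature series can ask *when*, relative to
conception, temperature matters.

`ssrlag` implements that analysis for aggregated historical registers of the
kind kept by nineteenth-century urban parishes: monthly counts of boys and
girls born, plus a homogenized monthly mean air-temperature series. The
package estimates conception months, assembles a lagged-temperature design,
fits penalized-spline binomial logistic additive models, and recovers a
distributed-lag profile of temperature effects with pointwise confidence
intervals. A seeded synthetic-data generator with known ground truth makes
every stage testable without any archival data.

## From birth months to a model frame

Aggregated registers record only the month of birth. We date each birth to
the 15th of its month and subtract 280 days (40 weeks, the conventional
human gestation length) with true calendar arithmetic — leap years included,
proleptic Gregorian throughout — to obtain a conception date; the conception
month is the calendar month containing that date. We deliberately do *not*
round to "nine months earlier": the day-level formula is authoritative, and
the two rules disagree for part of the year.

Each birth month's row then carries 19 monthly temperatures `mon[-9] ..
mon[+9]` relative to the conception month (lag 0 = conception month,
negative lags before conception, positive lags during pregnancy; lag +9 is
the birth month itself), plus the annual mean temperature of a reference
calendar year. Rows whose lag window or reference year is not fully covered
by the temperature record — in practice the first birth months, whose
conceptions predate the start of the station series — are dropped listwise
and counted; no imputation is attempted, since any rule would be invented
and the loss affects only the series edge.

Two conventions circulate for the annual covariate: the calendar year of
conception and the calendar year of birth. They differ for roughly a quarter
of births. `assemble_model_frame()` defaults to the conception year (the
covariate is, after all, motivated by conditions around conception) and
exposes `annual_year = "birth"` for the alternative; nothing downstream
changes.

## The model ladder

All models are binomial logistic additive models fitted to monthly
aggregates, `girls ~ Binomial(total, p)` with

* **M0**: `logit p = a + f_year(birth year) + f_month(birth month)` — a
  fully nonparametric trend and seasonal decomposition of the SSR series;
* **MT0**: M0 plus `f_temp(annual mean temperature)`;
* **MTA**: M0 plus a linear distributed-lag term
  `sum_l beta_l * temp[lag l]` over the 19 lags, regularized by the Almon
  polynomial constraint.

### Penalized spline engine

The smooths are cubic regression splines parameterised by their values at
knots, with the exact integrated-squared-second-derivative penalty; the
month smooth uses the cyclic variant with knots on `(0.5, 12.5)` so December
and January are distinct months yet the fitted effect and its first two
derivatives wrap smoothly across the year boundary. Basis dimensions default
to `k = 10` (year), `k = 8` (month) and `k = 10` (temperature); the penalty,
not `k`, controls the effective complexity, so these only need to be
generous. Each smooth is centred to sum to zero over the observed covariate
values; the intercept carries the overall level.

Every penalty is normalized to unit spectral norm so one log-lambda search
box serves all terms. By default each smooth also carries a *shrinkage*
penalty: the roughness penalty's null space (constant + linear for the
natural basis, constant for the cyclic one) is penalized with a weight one
order of magnitude below the weakest curvature eigenvalue. That weight is a
compromise we validated by simulation: strong enough that an absent term is
shrunk to effectively zero degrees of freedom at large lambda, weak enough
that a genuinely linear trend is not distorted at the lambdas the smoothness
criterion selects. An effective degrees of freedom (edf) of exactly 0 for a
term is therefore a reachable outcome, matching how such models report a
completely absent seasonal effect.

Fitting is penalized iteratively reweighted least squares (PIRLS) on the
aggregated binomial likelihood, converged when the penalized deviance
changes by less than 1e-8 relatively (at most 200 iterations, with step
halving as a safeguard; non-convergence is flagged, never silent).
Smoothing parameters minimise the Laplace-approximate REML criterion
(GCV is available as an alternative) by Nelder-Mead on log-lambda from
several starts, within log-lambda in [-25, 25]. With the unit-norm
penalties, those bounds span fits from effectively unpenalized to fully
shrunk. Against the reference GAM machinery in `mgcv` (used in the test
suite purely as an independent cross-check), REML fits of M0 on synthetic
data agree to fitted-probability RMSE below 1e-3 and to ~0.1 edf per term;
with all penalties at zero the fit equals `glm()` to 1e-6.

Per-term edf is the trace of the term's block of
`(X'WX + S_lambda)^{-1} X'WX`. Interval estimates use the Bayesian posterior
covariance `(X'WX + S_lambda)^{-1}`. The test of a smooth term against zero
is a Wald-type quadratic form in the term's coefficients, but computed with
the *frequentist* covariance of the penalized estimator and a pseudo-inverse
truncated at the term's bias-corrected edf rounded to an integer rank. The
choice of covariance matters: with the Bayesian covariance the statistic
deflates under heavy penalization and the test becomes severely
conservative for fully penalized (cyclic) terms; with the estimator's
sampling covariance, null rejection rates in our calibration simulations sit
at 6–8% at the 5% level for both the year and month terms — the test is
approximate and runs slightly above level, never silently below it. The
calibration study uses unshrunk penalized splines, because shrinkage is a
deliberate bias toward zero and its test is conservative by construction.

### The Almon distributed-lag sub-model

Nineteen adjacent monthly temperatures are strongly collinear, so the
unconstrained per-lag coefficients are essentially unestimable. The Almon
device constrains the lag-coefficient sequence to a degree-`d` polynomial of
the lag index: with transform matrix `T` (an orthonormalized polynomial
basis, `L x (d+1)`), the reduced design `(lag matrix) %*% T` contributes
only `d + 1` unpenalized columns to the model, and the per-lag coefficients
are recovered as `beta = T theta_hat` with delta-method covariance
`T Cov(theta_hat) T'` and pointwise 95% intervals `beta_l +/- 1.96 SE_l`.
Orthonormalization is purely for conditioning; `d = L - 1` reproduces the
unconstrained fit exactly (deviance agreement to 1e-6 in the test suite),
which is the key correctness check of the fold/unfold algebra.

The polynomial degree is a genuine modelling choice. The default is a cubic
(`d = 3`): the smooth single-trough-plus-rise shape that monthly-temperature
lag profiles of the SSR exhibit is representable by a cubic, and lower
degrees force symmetry the data may not have. `almon_degree_scan()` refits
across degrees and reports AIC so the choice is explicit rather than buried.
We impose no endpoint ("tail-to-zero") constraints: published lag tables in
this literature show nonzero edge estimates, and forcing zeros would
manufacture significance in the interior. Lag indexing — 0 = conception
month, negative before, positive after — is fixed package-wide and asserted
in tests.

## Climatological characterization

`climatology_summary()`, `linear_trend()` and `classify_thermal()` reproduce
the standard descriptive companion to such an analysis: monthly and annual
means and standard deviations, an ordinary-least-squares decadal trend with
a two-sided t-test at the 0.05 level, and a percentile classification that
assigns each year (per scope: annual and each calendar month separately) to
one of 11 ordered classes delimited by the 5, 10, 20, 30, 40, 60, 70, 80,
90, 95th percentile thresholds of a reference period.

The quantile estimator is linear interpolation between order statistics
(R's `type = 7`, the common default of mainstream statistical environments);
the boundary rule is upper-closed intervals, i.e. a value equal to a
threshold joins the lower band, and tied thresholds resolve to the middle of
the tied span — so a degenerate all-equal reference collapses to the middle
("normal", 40–60th percentile) class. Neither choice is canonical in the
literature; under a different estimator, class counts near band edges can
shift by about one year, which is why tests assert band indices and
occupancy proportions rather than named labels.

## The synthetic-data generator

`simulate_temperature()` draws a monthly series from a station climatology:
per-month means and standard deviations, plus a linear trend. The default
profile is calibrated to a mid-European (Poznań-like) station over
1848–1900: annual mean 7.5 °C, January mean −3.0 °C, July 18.1 °C, monthly
standard deviations from 1.2 °C (August) to 3.0 °C (January/February), and a
weak 0.1 °C/decade warming trend. Noise is independent Gaussian per month by
default — the fitted models treat temperature as an exogenous covariate, so
serial structure is not needed for recovery testing — with an optional AR(1)
knob for users who want serially correlated anomalies.

One consequence of independent monthly noise is worth knowing: the standard
deviation of simulated *annual* means is about 0.6 °C, whereas real station
series of this kind show about 0.8 °C, because real monthly anomalies are
positively correlated within a year. Relatedly, a 0.1 °C/decade trend that
is not statistically significant against sd-0.8 interannual noise over 53
years can test as borderline significant against the generator's thinner
annual noise. Passing recovery tests therefore demonstrate correctness of
the estimators under the stated generative model, not that real data would
yield the same significance calls.

`simulate_birth_series()` draws monthly girl counts as
`Binomial(births_per_month, plogis(eta))` where `eta` is a configurable
baseline + trend(birth year) + season(birth month) + lag-profile·temperature
structure — the generative analogue of MTA. Defaults mirror the study scale:
104 births per month (a 53-year register of ~66,000 births), baseline logit
−0.0556 (girl proportion ≈ 0.4861), and a ground-truth lag profile that is
an exact cubic in the lag index with a trough of ≈ −0.005 logit/°C around
lags −6..−3 and a small positive edge at +9. Making the true profile an
exact cubic is deliberate: the default fitted constraint (also cubic) then
contains the truth, so coverage statements about the per-lag intervals are
meaningful. All randomness flows through explicit integer seeds; there is no
hidden global state, and identical seeds give bitwise-identical series.

A subtlety the generator exposes: even with a zero seasonal term, a nonzero
lag profile induces a *marginal* seasonal pattern in the sex ratio, because
the lagged temperatures are themselves seasonal. M0 (which has no
temperature terms) will legitimately attribute that pattern to its month
smooth, while MTA absorbs it into the lag block and shrinks the month term.
Null-calibration simulations therefore use a zero lag profile.

## Problem sizes and numerical choices in the test suite

The shipped tests exercise the full pipeline at the scale of the motivating
study — about 620 retained months of ~100 births — with 200 replicates for
coverage (mean pointwise lag-CI coverage ~0.95–0.96), 150–200 replicates for
null calibration, 2,000 replicates for the trend test's size, and 1,000
simulated years for classification occupancy; smaller 18-year frames
(~200 months) serve the exact-oracle checks. These sizes keep the whole
suite within a few minutes on one core while leaving Monte-Carlo error well
inside the asserted bands. Tolerances: exact algebraic identities are
asserted at 1e-6 to 1e-10; Monte-Carlo quantities at 2–3 standard errors of
their replicate count.

## Known limitations

* The conception-date rule inherits the register's aggregation error: all
  births are dated to the 15th, all gestations to 280 days. Pre- and
  post-term births misassign the lag window by a month in either direction.
* The lag model is linear in temperature at each lag; exposure–lag–response
  surfaces (DLNM-style cross-bases) are out of scope.
* The smooth-term test is approximate; its size is calibrated at the few-
  percent level, not exact.
* With shrinkage smooths, REML under a strong *linear* signal settles on a
  moderately wiggly fit rather than edf ≈ 1 (one lambda must trade the null
  space against curvature); use `shrink = FALSE` when a clean linear-vs-
  smooth reading of edf matters. The reference implementation behaves the
  same way.
* The percentile classification's class counts near band edges depend on
  the quantile estimator by up to ±1 year.

## A worked synthetic run

```{r example, eval = FALSE}
temps <- simulate_temperature(climatology_profile(), seed = 1)
births <- simulate_birth_series(temps, scenario_config(seed = 2))
frame <- assemble_model_frame(births, temps)

m0 <- fit_m0(frame)
mt0 <- fit_mt0(frame)
mta <- fit_mta(frame)

tidy(mta, "smooth")      # edf and p per smooth
mta$lag_table            # per-lag coefficients with pointwise 95% CIs
autoplot(mta$lag_table)  # the lag-profile figure

classify_thermal(temps) |> plot_thermal_classes()
```
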