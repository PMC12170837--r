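---
title: "Estimating the temperature-attributable burden of obstructive sleep apnea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the temperature-attributable burden of obstructive sleep apnea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nightly obstructive sleep apnea (OSA) severity, measured by the
apnea–hypopnea index (AHI), varies substantially from night to night within
the same sleeper, and part of that variation tracks ambient temperature.
Given a long panel of nightly OSA indicators (AHI ≥ 15, and ≥ 30 for severe
OSA) with matched daily weather, three questions arise:

1. What is the shape of the association between daily ambient temperature
   and the probability of having OSA on the following night, allowing for
   delayed effects over several days?
2. How many additional OSA person-days does observed warming create,
   relative to a mid-20th-century temperature baseline?
3. What are those excess person-days worth in health (years of life lost,
   years lived with disability, DALYs) and in workplace productivity?

`osaheat` implements this pipeline end to end, together with a synthetic
cohort generator whose true exposure–response is known in closed form, so
every stage can be validated without access to proprietary panel data.

## The model

### Case-time-series design

Each participant's nightly series is divided into participant × year ×
month strata. Within a stratum the baseline risk is treated as a free
intercept, so only within-month variation identifies the temperature
effect — a self-matched design that removes all between-person confounding
and slow within-person drift. The nightly indicator is modelled with a
Poisson log-linear likelihood; with one intercept per stratum the intercepts
can be profiled out analytically. Writing \(Y_s\) for the stratum event
total and \(S_s(\beta) = \sum_{i \in s} e^{x_i'\beta}\), the profiled
log-likelihood is

\[
\ell(\beta) \;=\; \sum_i y_i \, x_i'\beta \;-\; \sum_s Y_s \log S_s(\beta),
\]

maximised by Newton–Raphson with step-halving (convergence when the maximum
absolute score is below `1e-8` or the relative log-likelihood change below
`1e-10`, at most 100 iterations). Strata with zero events contribute
nothing and are dropped. With a binary nightly outcome and a log link, the
exponentiated coefficients are risk ratios. The model-based covariance (the
inverse profiled Hessian) is reported; because a Bernoulli variance is
smaller than the Poisson variance at the same mean, the resulting intervals
are mildly conservative, which the null-coverage test quantifies.

### Distributed-lag cross-basis

Temperature on day \(d\) and the four preceding days affects the night
beginning on day \(d\). The exposure dimension uses a natural cubic spline
with 4 degrees of freedom — internal knots at the 25th/50th/75th percentiles
of the fitted exposures, boundary knots at the range — and the lag dimension
uses one indicator per lag (lags 0–4). The cross-basis column \((j, \ell)\)
is basis function \(j\) evaluated at the lag-\(\ell\) exposure, centred at
the reference temperature (default: the 25th percentile), so the cumulative
log risk ratio at the reference is identically zero. The cumulative curve
sums coefficients over lags; with the indicator lag basis this is an exact
column-group sum, and contrasts such as the 99th-vs-25th percentile
(27.3 vs 6.4 °C) are linear functionals of the coefficients with
delta-method intervals (z = 1.959964).

The indicator lag basis is the least-assumptive choice for a 5-day window;
smooth lag bases matter when windows stretch to weeks. Adjustment terms are
a 4-df day-of-year spline, day-of-week indicators, optional 4-df splines of
meteorological covariates, and optionally a 4-df spline of within-user
sleep-time variation. An odds-ratio-to-risk-ratio conversion
(`RR = OR / (1 - p0 + p0 OR)`) is provided for placing logistic summaries
from other designs on the same scale; its baseline risk defaults to the
outcome prevalence among fitted nights within ±1 °C of the reference.

### Attribution and burden

A 365-entry day-of-year climatology (1950–1990 means, Feb 29 dropped) is
the counterfactual. For year \(y\), the daily excess risk is
\(RR(T_{d,y}) - RR(T^{hist}_d)\), computed on the risk-ratio scale.
Temperatures outside the curve's grid are clipped to the grid ends (flat
extrapolation) and counted. Excess person-days are
\(\sum_d \text{excess}_d \times p_0 \times APOP\).

The burden equations follow the published forms exactly, including their
annual-mean (\(\tfrac{1}{365}\sum\)) structure with daily rates:

- **YLL** = mean excess × \(p_0\) × APOP × (MVA death rate × RR\(_{MVA}\)) × RLE,
  with RR\(_{MVA}\) ∈ {0.5, 1.0, 1.5} for the lower/mean/upper bound. The
  MVA death rate is read as a *daily* rate of fatal motor-vehicle accidents,
  the reading most consistent with the surrounding prose. Dimensionally the
  product is "excess person-years at risk × daily death rate × years per
  death"; we record this reading rather than silently rescaling it.
- **YLD** = mean excess × \(p_0\) × APOP × DW × L, DW ∈ {0.05, 0.08, 0.11},
  L = 1 day.
- **DALY** = YLL + YLD, valued at {1, 2, 3} × GDP per capita.
- **Presenteeism/absenteeism** = (235/365) × Σ excess × \(p_0\) ×
  LF\(_{adj}\) × rate, with rates 6.8% and 2.1% and the labor force reduced
  by half its part-time share. **Labor loss** = (PRES + ABS) × GDP per
  capita employed / 365.

Wellbeing bounds come from the parameter triplets (each output is linear in
its parameter, so bounds are exact rescalings); productivity bounds come
from re-running the attribution at the curve's pointwise 95% CI envelope —
the published bound mechanism for these outputs is unstated, and we chose
the envelope because the excess risk is the only stochastic input to
Eqs. for presenteeism/absenteeism. Negative day counts are allowed: they
arise when a cooler-than-baseline year (or the lower envelope) reduces the
burden.

Projection holds 2023 prevalence and population constant in the primary
mode; the sensitivity mode applies a population forecast and ramps
prevalence linearly from 1.0× (2023) to 1.3× (2050), constant afterwards —
the published statement gives only the endpoint, so a linear ramp is the
minimal interpolation.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study conditions
for every simulation-based check:

- **Weather**: daily mean = annual mean + seasonal sinusoid (peak day 197) +
  stationary AR(1) noise + linear trend; min/max = mean ∓ 4 °C. Defaults
  (mean 12.5 °C, amplitude 9.2 °C, noise sd 3.6 °C, AR 0.6) were chosen so
  the empirical 25th/99th percentiles sit near the study's 6.4/27.3 °C
  contrast temperatures. Feb 29 is generated but flagged, and dropped by
  the climatology.
- **Panel**: nightly indicators are Bernoulli with
  \(\log p = \log p_0 - \sigma_u^2/2 + a_u + s(\text{doy}) + \text{dow} +
  \sum_\ell \theta_\ell\, g(T_{d-\ell})\), where \(a_u \sim N(0, \sigma_u^2)\)
  (default σ = 0.3) and \(g\) is a smooth monotone transform expressed in
  the *same* spline basis the fitter uses, so the fitted model is correctly
  specified and the generative cumulative risk ratio
  \(\exp\{\sum_\ell \theta_\ell [g(t_1) - g(t_0)]\}\) is available in closed
  form. `calibrate_lag_effects()` rescales \(\theta\) so this equals any
  requested value exactly. The log link (not logit) is used deliberately:
  it makes the generative contrast a risk ratio — the estimand of the
  conditional Poisson fit — rather than an odds ratio; probabilities are
  capped at 0.995 and cap hits counted (zero at the default settings). A
  piecewise-linear transform is available as a deliberately mis-specified
  truth for robustness checks.
- **Defaults** mirror the study conditions: baseline nightly probability
  0.254 (OSA) and 0.089 (severe), total sleep time Normal(7.4 h, 0.8 h) —
  which puts ~0.13% of nights below the 5-hour AHI threshold by chance —
  declining lag shares over lags 0–4, and per-user RNG substreams so
  enlarging a cohort never perturbs existing users.

What the generator does *not* emulate: real geography and multi-country
heterogeneity, device-level AHI measurement error, within-user
autocorrelation of outcomes beyond what strata induce, and non-random device
attrition. Passing recovery tests therefore demonstrate the estimator's
correctness under the stated generative model, not robustness to every
feature of real panels; the temperature-dependent missingness option and the
piecewise truth exercise two specific departures.

## Numerical choices and edge cases

- Spline knots are frozen in a `spline_spec` and shared between generator,
  fitter, and curve prediction; knots falling on ties (zero-inflated
  covariates such as precipitation) fall back to quantiles of the distinct
  values.
- Collinear design columns are removed by rank detection on the Gram
  matrix with a warning; cross-basis columns are protected and trigger an
  error instead.
- Rows with missing outcome (AHI unavailable on short-sleep nights) are
  dropped before stratum bookkeeping (complete-case within stratum); the
  first `max_lag` nights per user are dropped unless the panel carries
  pre-period lag columns.
- Curve evaluation refuses extrapolation beyond the boundary knots by
  default; attribution clips scenario temperatures to the grid ends and
  logs the count.
- Reported person-day and year totals are kept in floating point and
  rounded only at serialization.

## Problem sizes used in validation

The estimator-recovery checks use 20 replicate cohorts of 2,000 users ×
365 nights (14.6 million nights in total per outcome), the null-coverage
check uses 100 replicates of 40 users × 365 nights, and the oracle
equivalence checks use panels of up to 50 strata, where the absorbed fit is
compared against an explicit stratum-dummy Poisson fit to 1e-6. These sizes
give Monte-Carlo error comfortably below the tolerances they are tested
against while keeping a full run on a single CPU within minutes.

## Known limitations

- The Poisson working likelihood on binary outcomes yields conservative
  intervals at moderate prevalences; a conditional-logistic alternative
  would be exact but loses the closed-form stratum absorption.
- The attribution treats the exposure–response curve as stationary over
  150 years (no acclimatisation or adaptation).
- Country parameters are treated as exact; only the MVA risk ratio,
  disability weight, DALY value, and curve uncertainty propagate to bounds.
- The pipeline accepts one daily series per country-scenario; forming
  multi-model ensemble medians is upstream of this package.
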