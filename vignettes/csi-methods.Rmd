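---
title: "Combined stress index modelling and forecast verification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined stress index modelling and forecast verification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Summer heat and drought are the dominant climate drivers of interannual
maize yield variability across much of Europe. This package implements a
country-level statistical chain that (i) condenses gridded weather into two
agro-climatic predictors, (ii) calibrates a *Combined Stress Index* (CSI)
against national yield statistics with honest out-of-sample evaluation, and
(iii) asks whether ensemble seasonal re-forecasts, after bias correction,
carry usable probabilistic skill for *low-yield* events. Because the
observational inputs (a gridded daily meteorological analysis, national
yield records, a coupled-model re-forecast set) cannot be redistributed, a
synthetic generator with known ground truth stands in for them; every stage
is tested against that truth.

## Predictors

**Heat degree days.** For each grid cell and year,

$$HDD_{JJA} = \sum_{i=1}^{N} \max(T_{\max,i} - T_{thr},\, 0),$$

summing daily maximum-temperature exceedances over the June–August days.
The threshold `t_thr` defaults to 30 °C, just above the optimum range for
maize growth processes, so the index accumulates a wide band of deleterious
temperatures rather than only rare extremes. A cell-summer with more than
5% missing days is invalidated and dropped, with the crop weights
renormalised over the remaining cells — the tolerance keeps the behaviour
deterministic where the data sources are silent.

**SPEI.** The standardised precipitation–evapotranspiration index
aggregates the monthly climatic water balance $D = P - PET$ over $k \in
\{1,2,3\}$ months ending in June, July or August, fits a three-parameter
log-logistic distribution to the reference-period balances by unbiased
probability-weighted moments (the standard SPEI formulation), and maps each
year through the fitted CDF to a standard-normal deviate. If the PWM fit is
invalid (the shape estimate must exceed 1 for finite moments), an empirical
Gringorten plotting-position transform is used instead. Probabilities are
clamped to $[5\times10^{-4}, 1-5\times10^{-4}]$ so unseen extremes stay
finite. PET uses Thornthwaite's temperature-only formulation (monthly heat
index, cubic exponent, mid-month daylength correction): it matches the
available inputs, and nothing in the chain is sensitive to the PET level —
only to its anomalies. The reference period for the fit is the full
analysis period, matching the single-period study design.

**Aggregation order.** Both indices are computed per grid cell and *then*
averaged to country level with harvested-maize-area weights. Averaging
climate first would smooth out exactly the local extremes the indices are
meant to capture; the alternative reading (aggregate climate, then index)
is not implemented.

## De-trending

Decadal trends in yields reflect breeding, management and socio-economic
change; trends can also leak into the climate indices. A quadratic
polynomial in centred year is therefore removed from `log(yield)` and,
with the same procedure, from HDD and SPEI (identity scale — both can be
zero or negative). Yields and HDD are additionally standardised; SPEI is
de-trended only, being standardised by construction. Centring the year
makes the fit invariant to the calendar origin, and removal is idempotent.
The Mann–Kendall test (tie-corrected normal approximation) is reported as
a diagnostic; removal is unconditional by default because the anomaly
definition, not trend significance, is what downstream stages rely on. A
`gate_on_mk` switch restricts removal to Mann–Kendall-significant trends
for sensitivity analyses.

## The CSI model

For each country,

$$Y^{std,*}_t = a\,SPEI^{*}_{opt,t} + b\,HDD^{std,*}_{JJA,t} + \varepsilon_t
 = CSI_t + \varepsilon_t,$$

fitted as an intercept-free bilinear *ridge* regression on the centred,
standardised series — the penalty stabilises the fit under the strong
negative covariance of the two predictors (hot summers are dry summers).
The 2×2 normal equations are solved in closed form.

Predictive performance is the leave-one-out
$$Q^2 = 1 - \frac{\sum_t (\hat y_t^{(-t)} - y_t)^2}{\sum_t (y_t - \bar y)^2},$$
where $\hat y_t^{(-t)}$ comes from a model refitted without year $t$.
Within each training fold the ridge penalty is re-selected from the
log-spaced grid $10^{-3}, \dots, 10^{2}$ by an *inner* leave-one-out PRESS
(computed exactly through the hat-matrix identity), i.e. nested
cross-validation: the penalty choice never sees the held-out year, so the
reported $Q^2$ is not optimistically biased by tuning. Whether the original
analysis fixed or tuned its penalty is not documented; nesting is the
conservative choice.

The SPEI aggregation window (timescale × ending month, nine candidates) is
chosen per country by maximising this leave-one-out $Q^2$; exact ties break
to the smaller timescale, then the earlier month, so results are
deterministic. Significance of $Q^2$ is assessed by a permutation test
(default 500 year-permutations of the yield series, re-running the nested
LOO at the chosen window; significant at $\alpha = 0.05$ when the observed
$Q^2$ is positive and exceeds the null's 95th percentile). The original
study marks significance without naming a test; a permutation test makes
the fewest distributional assumptions and respects the selection procedure.
Countries with fewer than 20 yield years or non-significant models are
excluded from forecast verification, with recorded reasons.

## Bias correction

Ensemble re-forecast variables (monthly precipitation, monthly mean
temperature, June–August daily maximum temperature) are corrected by
non-parametric quantile mapping: empirical quantiles at 21 evenly spaced
probabilities on each side, members pooled on the forecast side,
stratified per variable × start month × calendar month × grid cell (daily
maxima pool the days within each month). The transfer is piecewise-linear
between knots; beyond the outermost pair a constant offset is applied, so
unseen extremes behave boundedly; corrected precipitation is floored at 0.
Quantile knots use the inverse empirical CDF with an explicit index rule,
which is invariant under pooling identical members — an ensemble that
already matches the observations maps onto the exact identity, and the
perfect-forecast limit propagates exactly through the whole chain.
Correction is in-sample (fitted on the full period) by default, as
cross-validated correction is not documented for the source analysis; the
monotone transfer preserves member rank order within each stratum.

## Forecast CSI and verification

Member indices are computed from the corrected fields with the same code
path as the observations. SPEI windows that begin before the forecast
start month splice the observed monthly values for the pre-start months
(monitoring data are available at initialisation time), and the
Thornthwaite heat index likewise uses the member months spliced into the
observed year. Member balances are transformed with the
*observation-fitted* cell distributions, and member indices are converted
to anomalies with the observation-derived trend fits and standard
deviations — the model is calibrated only against observations and one
model is applied to both.

The low-yield event `CSI_low` is the observed CSI falling below its 25th
percentile (linear interpolation between order statistics) over the full
period, per country; the forecast probability is the fraction of members
below that threshold. Scores:

* **Correlation** of ensemble-mean CSI with observed CSI and with
  standardised yield anomalies (two-sided t-test, $p < 0.05$; no
  autocorrelation correction — the series are annual).
* **Reliability**: forecasts pooled across significant countries with
  maize-cropland-area weights, grouped into 5 probability bins; per-bin
  weighted forecast probability and observed frequency; a bin-count-
  weighted linear regression summarises the diagram, with a 75%
  pair-resampling bootstrap interval (1000 replicates) on the slope.
  The climatological frequency and the no-skill line (midway to the
  diagonal, the positive-Brier-skill boundary) are reported alongside.
* **ROC / ROCSS**: a decision threshold stepped through the forecasts in
  20% increments; hit rate $j/(j+l)$ against false-alarm rate $k/(k+m)$,
  curve closed at (0,0) and (1,1), trapezoid area, $ROCSS = 2\,area - 1$,
  with the same bootstrap interval.
* **ETS** per country and member-fraction threshold (50–80%):
  $ETS = (j - j_r)/(j + k + l - j_r)$ with
  $j_r = (j+l)(j+k)/(j+k+l+m)$; undefined tables (zero denominator) are
  reported as missing. Start months are scored separately.
* **Stress-area fractions**: per year, the maize production area of
  significant-model countries with drought only ($SPEI^* < -1$,
  $HDD^{std,*} < 1$), heat only ($SPEI^* > -1$, $HDD^{std,*} > 1$) or
  combined stress ($SPEI^* < -1$, $HDD^{std,*} > 1$), as exclusive
  fractions of the total considered area.

## The synthetic generator

`synth_config()` fixes the study conditions; the defaults are chosen once
and define what the tests mean.

* **Period and grid**: 30 years (a 1981–2010-style record; at least 20
  years, mirroring the yield-series inclusion rule) on a 6×6 one-degree
  grid split into 4 contiguous country strips with gamma-distributed
  harvested-area weights.
* **Weather**: harmonic seasonal cycles (mid-summer mean daily maximum
  ≈27.5 °C at the central latitude, so the 30 °C threshold sits inside the
  distribution: hot years accumulate large HDD, cool cell-years can reach
  zero) plus spatially correlated *monthly* anomaly fields (exponential
  correlation, e-folding 3 cells) plus cell-level noise. Month-level
  rather than year-level anomalies are essential: a single annual draw
  would make all nine SPEI windows nearly collinear and window recovery
  meaningless. Temperature and precipitation anomalies are coupled at
  −0.3, emulating hot–dry compounding. Precipitation is generated
  directly at the monthly scale (the chain consumes nothing finer) and
  floored at zero.
* **Yields**: $\log y_t = \log 6 + c_1 t + c_2 t^2 + s\,(0.4\,SPEI^*_t -
  0.6\,HDD^*_t + e_t)$ with the true predictors computed by the production
  index code at the generating window (SPEI2 ending July), noise
  $e_t \sim N(0, 0.5)$ and scale $s = 0.15$ so yield swings are an
  agronomically plausible 10–20%. The scale multiplies signal and noise
  jointly, so it cancels from every standardised quantity; the recoverable
  truth is the standardised effect pair (0.4, −0.6).
* **Re-forecasts**: 10 members, 4-month windows from 1 May or 1 June.
  Each member's anomaly is $\rho\,(\text{observed anomaly}) +
  \sqrt{1-\rho^2}\,(\text{independent draw from the same weather model})$,
  then shifted (+2 °C, +10 mm) and inflated (×1.5) so quantile mapping has
  work to do. $\rho$ (`skill_rho`) is the single knob contrasting
  realistic (≈0.8) with climatological (0) land-surface initialisation.
  Experiments sharing a start month share member noise, so skill
  comparisons use common random numbers.

What the generator does *not* emulate: daily precipitation, snow and soil
state, lead-time-dependent drift, non-Gaussian heat-wave tails,
sub-national yield heterogeneity, or irrigation buffering (the mechanism
behind non-significant CSI models in parts of real Europe). Passing tests
therefore demonstrate that the *statistical machinery* is correct and
recovers known structure — not that real-world skill would match.

One structural consequence worth knowing: with the member construction
above, members correlate $\rho^2$ with each other but $\rho$ with the
truth, so intermediate-skill ensembles are over-dispersed after
climatology matching and their count-weighted reliability slope can
overshoot 1. Discrimination (ROCSS) is strictly monotone in `skill_rho`;
the reliability slope is monotone only up to its bootstrap uncertainty,
and the test suite checks exactly that.

## Numerical choices

* Ridge: closed-form 2×2 solve; degenerate predictors error only at
  $\lambda = 0$; exact LOO via the hat-diagonal identity for the inner
  penalty search.
* SPEI: PWM validity requires shape > 1; otherwise the empirical fallback.
  Probability clamping bounds the index at ±≈3.3.
* Quantile maps with tied knots (dry months) collapse duplicated source
  quantiles, keeping the transfer monotone non-decreasing.
* The event threshold and all quantiles use deterministic rules (linear
  interpolation for the event quantile, inverse ECDF for mapping knots),
  and every stochastic routine takes an explicit seed.
* Window ties break lexicographically (smaller $k$, earlier month).

## Problem sizes

The shipped analysis runs 4 countries × 30 years on a 6×6 grid with
500-permutation significance tests and 1000-replicate bootstraps (about
half a minute end to end). The test suite exercises 100-replicate
coefficient/window-recovery ensembles at 30 years and a 200-year two-country
run for the skill-ordering property; these sizes give Monte-Carlo noise
comfortably inside the asserted tolerances.

## Limitations

National yield statistics conflate climate with policy and management;
the quadratic trend is a blunt instrument for that. The CSI is linear and
two-predictor by design — no circulation indices, no nonlinear stress
interactions, no spatial pooling across countries. In-sample quantile
mapping and a single 30-year period mean real-data skill estimates would
carry more uncertainty than the synthetic analogue suggests. Stationarity
of the yield–stress relationship is assumed throughout; recalibration
would be required under changed varieties or management.
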