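# csiforecast

Country-level **Combined Stress Index (CSI)** modelling of maize yield
variability from summer heat and drought, and probabilistic verification of
CSI seasonal re-forecasts.

Who this is for: agro-climatologists and forecast-verification people who
want a tested, reproducible implementation of the full chain — index
construction, cross-validated calibration against national yields, ensemble
bias correction, and reliability/ROC/ETS scoring of low-yield forecasts —
with a synthetic data generator so everything runs without any proprietary
observational or re-forecast dataset.

## The method

Two agro-climatic predictors are computed per grid cell and crop-area
weighted to country level:

* heat degree days, `HDD_JJA = Σ max(Tmax_i − 30 °C, 0)` over June–August
  days;
* SPEI, the climatic water balance `P − PET` aggregated over 1–3 months
  ending in June/July/August, transformed to a standard-normal deviate via
  a PWM-fitted log-logistic distribution (Thornthwaite PET).

After quadratic de-trending (log scale for yields) and standardisation, a
bilinear ridge regression defines the index:

```
Y*std_t = a·SPEI*_opt,t + b·HDD*std_t + ε_t  =  CSI_t + ε_t
```

The SPEI window is optimised per country by leave-one-out predictive
performance `Q² = 1 − Σ(ŷ_t^(−t) − y_t)² / Σ(y_t − ȳ)²`, with the ridge
penalty selected by nested cross-validation and significance from a
permutation test. Ensemble re-forecasts are quantile-mapped onto the
observed climatology, pushed through the calibrated models, and scored as
probabilistic forecasts of `CSI_low` (CSI below its 25th percentile):
reliability diagrams with count-weighted regression, ROC skill score
(`ROCSS = 2·area − 1`) with 75% bootstrap intervals, and the Equitable
Threat Score `ETS = (j − j_r)/(j + k + l − j_r)`, `j_r = (j+l)(j+k)/n`.

See `vignettes/csi-methods.Rmd` for the full methods account.

## Worked example

```r
library(csiforecast)

cfg     <- synth_config(seed = 2026)        # 4 countries, 30 years, 6x6 grid
climate <- generate_climate(cfg)
mask    <- generate_crop_mask(cfg)
yields  <- generate_yields(climate, mask, cfg)$yields

cal <- calibrate_csi(climate, mask, yields, B = 500, seed = 2026)
cal$q2_table
#>  country        q2 significant reason
#>       C1 0.5836281        TRUE   <NA>
#>       C2 0.5812750        TRUE   <NA>
#>       C3 0.6589864        TRUE   <NA>
#>       C4 0.5145561        TRUE   <NA>

fcs <- list(INIT05 = generate_forecasts(climate, cfg, 5, skill_rho = 0.8),
            CLIM05 = generate_forecasts(climate, cfg, 5, skill_rho = 0))
ver <- verify_forecasts(cal, climate, mask, fcs, seed = 2026)
sapply(ver$reports, function(r) r$roc$rocss)
#>     INIT05     CLIM05
#>  0.8249107 -0.1409993
```

Reading this: all four synthetic countries get significant CSI models with
leave-one-out `Q²` between 0.51 and 0.66 — i.e. the index explains half to
two-thirds of interannual yield variability out of sample, the regime in
which the method is meant to operate. The realistic-initialisation
analogue (`skill_rho = 0.8`) discriminates low-yield years almost
perfectly (ROCSS 0.82), while the climatological analogue (`skill_rho = 0`)
has none, matching the INIT/CLIM contrast the verification machinery is
designed to expose.

The full analysis lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R       # synthetic climate, crop mask, yields
Rscript analysis/02_observed_csi.R   # calibration, Q2 table, stress areas
Rscript analysis/03_forecast_skill.R # bias correction + verification
```

Each step prints a short narrative and writes tidy tables under `results/`
(yields, Q² table, index/CSI series, stress-area fractions, reliability
bins, ROC points, ETS, correlations, plus JSON model/report bundles with
provenance).

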