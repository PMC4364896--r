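# pulsepop

Consumer–resource dynamics driven by climate-predicted resource pulses.

Masting trees set huge seed crops in occasional years, and each pulse fuels
an outbreak of seed-eating consumers. For invasive house mice in New
Zealand beech forest those outbreaks cascade onto native fauna, so
managers need warning *before* the seed falls. `pulsepop` is an R package
plus analysis workflow for that problem, built for ecologists working on
pulsed-resource consumer systems:

* **Seedfall from climate.** The crop in year *y* is predicted from the
  change in mean summer temperature between the two preceding summers,
  log₁₀(F_y + c) = a + b·ΔT_y with ΔT_y = T_{y−1} − T_{y−2} (an
  absolute-temperature alternative is included for comparison).
* **A mechanistic consumer–resource ODE.** dM/dt = (α g(F) − μ₁ − μ₂M)M
  and dF/dt = S(t) − hF − g(F)M, with the annual crop delivered over the
  first quarter of a February-start year, seed reset at each year start,
  and a choice of functional responses g(F): Holling I, Ivlev, Holling II,
  uncapped. Compiled fixed-step RK4 integration with quarter-aligned
  segments.
* **Fitting and uncertainty.** RMSE minimisation against quarterly
  trap-catch indices (multi-start Nelder–Mead), nonparametric
  observation-resampling bootstrap CIs, AICc model comparison.
* **Outbreak thresholds.** 1000-year simulations summarised as spring
  (August) peak abundance and February→August rate of increase, each
  regressed on ΔT and log₁₀ seedfall with 4-parameter logistic versus
  linear fits compared by AICc.
* **Mast classification and climate scenarios.** Standardized-deviate
  mast flags, minimum-predictor climate thresholds, mean/variance bias
  adjustment of scenario temperature series, and mast-frequency
  statistics.
* **A synthetic-data generator** reproducing the statistical structure of
  the field system, so the whole pipeline is testable without any data
  download.

## Worked example

```r
library(pulsepop)

# synthetic field system: 43-yr seedfall record, 25-yr quarterly record
fx <- make_fixture(fixture_config(seed = 1))

# how predictable is the crop from climate?
fit_seedfall_regression(fx$temps, fx$seedfall, mode = "dT")
#> log10(F + 1) = 0.557 + 0.728 * (T[y-1] - T[y-2])
#>   r^2 = 0.670, p = 1.99e-11, residual SD = 0.432, n = 43

# fit the Ivlev consumer model to the quarterly index
fit <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev")
fit
#> <fit_result> ivlev (simplified structure), n = 100, k = 5
#>   RMSE = 0.3910 C/100TN, Pearson r = 0.985, AICc = -174.99
#>    c = 6.8, shape = 0.979, mu1 = -1.1, mu2 = 0.686, h = 9.95

equilibrium_abundance(fit$params)   # background abundance between masts
#> [1] 1.607747
```

The regression says a one-degree rise between the two preceding summers
multiplies the expected crop about five-fold (10^0.73); the consumer fit
recovers the generating dynamics (feeding saturation near one seed m⁻²,
background equilibrium ≈ 1.6 C/100TN, seed half-life ≈ 3.6 weeks).

The numbered scripts under `analysis/` run the full workflow (simulate →
fit all four functional responses → seedfall/mast analysis → 1000-year
outbreak thresholds → climate scenarios), printing what each step found
and writing tables under `results/`. On the default fixture the capped
responses tie within ~10 AICc units while the uncapped response loses by
~280; in the 1000-year run the logistic beats the line in all four
response/predictor pairings (ΔAICc ≈ 260–2500), giving the management rule
of thumb: ΔT below 0 °C, no outbreak expected; above 1 °C, expect one.

## Layout

```
R/              package code (time series, seedfall/mast models, ODE core,
                fitting, outbreak analysis, synthetic data)
src/            compiled RK4 integrator (Rcpp)
analysis/       numbered workflow drivers (01-05)
scripts/        acceptance.R
tests/testthat/ unit, property and end-to-end scientific tests
vignettes/      methods vignette (model, assumptions, numerics, limits)
```
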