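---
title: "Modelling consumer outbreaks driven by climate-predicted seed pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling consumer outbreaks driven by climate-predicted seed pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsepop)
```

## The problem

Masting trees — southern beech in New Zealand is the motivating case — set
very large seed crops in occasional, loosely synchronised years. Each pulse
of seed fuels an outbreak of seed-eating consumers; for invasive house mice
(*Mus musculus*) in beech forest those outbreaks cascade onto native fauna
through elevated predation, so managers need warning of an outbreak *before*
the seed falls. `pulsepop` implements a pipeline for exactly that question:

1. predict the annual seed crop from summer temperature alone,
2. drive a mechanistic consumer–resource model with the predicted crop,
3. turn the simulated dynamics into simple outbreak-warning thresholds, and
4. ask how warming scenarios change mast frequency.

## The seedfall model

The predictor of the crop in year $y$ is not the temperature itself but the
*change* in mean summer (January–March) temperature between the two
preceding summers, $\Delta T_y = T_{y-1} - T_{y-2}$:

$$\log_{10}(F_y + c) = a + b\,\Delta T_y + \varepsilon_y,$$

with $F_y$ the crop (seeds m⁻²). An absolute-temperature alternative
($T_{y-1}$ as the predictor) is retained for comparison; on both the
original field system and our synthetic records it explains far less
variance, and under a warming trend it saturates absurdly (nearly every
year crosses its mast threshold) whereas $\Delta T$ is trend-stationary.

Two conventions are deliberately exposed as configuration rather than fixed:

* **Zero-crop handling.** Seedfall records contain true zeros, so the log
  transform needs an additive offset $c$, default 1 seed m⁻², subtracted
  again on back-transform with flooring at zero. Whether the original
  regression used an offset or dropped zero years is not documented, so the
  offset is a parameter (`log_offset`), and exact-inversion tests use
  `log_offset = 0` where flooring would otherwise bite.
* **SD convention.** Standardized deviates use the sample SD ($n-1$)
  throughout.

Mast years are classified from standardized deviates
$AD_y = (F_y - \bar F)/\mathrm{sd}(F)$, with threshold
$AD_\mathrm{thres} = \min_y |AD_y|$ and a *strict* inequality
$AD_y > AD_\mathrm{thres}$ (ties are not masts). From the mast years the
climate thresholds $T_\mathrm{thres} = \min T_{y-1}$ and
$\Delta T_\mathrm{thres} = \min \Delta T_y$ are extracted; scenario series
are screened against them after an affine bias adjustment that matches the
scenario's mean and SD to the reference record over their overlapping years
(grid-interpolated scenario temperatures run cooler and flatter than
station records, so moment matching is required before thresholds
transfer).

## The consumer–resource model

Mouse abundance $M$ (captures per 100 trap-nights) and available seed $F$
(seeds m⁻²) evolve in continuous time over a February-start year:

$$\frac{dM}{dt} = \bigl(\alpha\,g(F) - \mu_1 - \mu_2 M\bigr)M, \qquad
  \frac{dF}{dt} = S(t) - hF - g(F)M,$$

where $S(t)$ delivers the annual crop at a constant rate over the first
quarter (February–April) and $F$ is reset to zero at each year start (seed
is not carried over; germination and decay finish the crop within the
year). Four functional responses $g(F)$ are available: Holling I
(`piecewise`, $c_1\min(F,K)$), Ivlev (`ivlev`,
$c_2(1-e^{-eF})$), standard Holling II (`holling2`, $c_2F/(F+K)$) and
`uncapped` ($c_1F$).

Key parameter meanings and defaults (the reference Ivlev set):

| symbol | meaning | units | value |
|---|---|---|---|
| $c_2$ | maximum per-capita feeding rate | seeds m⁻² mouse⁻¹ yr⁻¹ | 6.74 |
| $e$ | foraging efficiency | (seeds m⁻²)⁻¹ | 1.08 |
| $\mu_1$ | density-independent rate (growth if negative) | yr⁻¹ | −1.23 |
| $\mu_2$ | density-dependent rate | mouse⁻¹ yr⁻¹ | 0.76 |
| $h$ | external seed-loss rate | yr⁻¹ | 9.48 |

Two consequences of this parameterisation are useful sanity anchors: with
no seed the population follows logistic growth towards
$-\mu_1/\mu_2 \approx 1.6$ C/100TN, and seed decays with half-life
$\ln 2 / h \approx 3.8$ weeks, depleting the bank below 5% within six
months. (A half-life of "about six weeks" is sometimes quoted for
$h \approx 9$; $\ln 2/9.18$ is 3.9 weeks, and we report the arithmetic
value.)

**Structure choice.** Fitting the full model is unstable: abundance data
constrain only the product $\alpha\,g(F)$, and the consumption term
$g(F)M$ in the resource equation is weak relative to $hF$, so bootstrap
replicates wander along the $\alpha$–$c$ ridge (a property the test suite
asserts). The *simplified* structure — $\alpha = 1$ and no consumption
feedback — is therefore the default for every headline fit, and is what
the reported parameter values refer to.

## Numerics

The printed delivery condition for $S(t)$ in the source system is
internally inconsistent; we implement delivery while the fractional part of
$t$ lies in $[0, 0.25)$, which makes the rate integrate exactly to the
annual crop.

The integrator is a classical fixed-step 4th-order Runge–Kutta scheme
(default $dt = 1/400$ yr), compiled, integrating each quarter as a separate
segment so the forcing discontinuity and the year-start reset fall exactly
on segment boundaries — adaptive error control misbehaves across such
jumps. One genuine subtlety: at the start of a delivery quarter $F$ climbs
from 0 through the functional response's saturation scale within a time of
order $1/S$, which for very large crops is *narrower than the step*. The
first two base steps of each delivery quarter are therefore substepped
(64- and 8-fold), restoring clean 4th-order convergence; halving $dt$
changes quarterly extractions by well under $10^{-4}$ C/100TN. States are
floored at zero after each step (with a counter) to guard overshoot near
extinction, and the integrator is verified against closed forms — the
linear forced resource equation and seed-free logistic growth — and
against an independent adaptive solver (`deSolve::lsoda`).

## Fitting and uncertainty

The objective is the RMSE between quarter-start model abundances and the
observed quarterly index, with the initial abundance pinned to the first
observed February value. Minimisation is multi-start Nelder–Mead (20 seeded
starts by default) on a logistic box-transformed scale with bounds
$c \in (0, 100]$, shape $\in (0.01, 50]$, $\mu_1, \mu_2 \in [-10, 10]$,
$h \in [0, 30]$; positive parameters are searched on a log scale. On
noise-free synthetic data the generating parameters are recovered
essentially exactly (the generator and objective share the integrator, so
the optimum is a true zero of the objective).

Uncertainty comes from a nonparametric bootstrap: observation-level case
resampling with replacement (entering the objective as multiplicity
weights, 100 replicates by default), refits warm-started from the point
estimate plus random extra starts, and percentile 95% intervals.
Missing quarterly sessions are simply skipped by the objective rather than
imputed. Model variants are compared with a least-squares AICc,
$n\ln(\mathrm{RMSE}^2) + 2K + 2K(K+1)/(n-K-1)$ with the error variance
counted in $K$; only AICc *differences* on identical data are
interpreted, since the absolute value depends on the unstated variance
convention of any external comparison.

## Outbreak thresholds

The long-horizon analysis (`run_step4()`) simulates 1000 years of
temperature → $\Delta T$ → seedfall → consumer dynamics and summarises each
year by the spring (August) peak and the February→August rate of increase
(ratio of quarter-start extractions, denominator floored at 0.1 C/100TN so
zero-index years remain usable). Each response is regressed on $\Delta T$
and on $\log_{10}$(seedfall) with a *4-parameter* logistic — both
asymptotes free, because the lower plateau (the seedless-year background)
is distinctly nonzero — against a straight-line alternative. Across all
four pairings the logistic wins by enormous AICc margins (hundreds to
thousands of units on the default 1000-year run), which is
the quantitative form of the management rule of thumb: below
$\Delta T \approx 0$ no outbreak, above $\Delta T \approx 1\,°$C an
outbreak is near-certain. Fits are on the raw response scale (a log-scale
response is a configuration choice left to the user).

## What the synthetic generator does and does not emulate

The generator reproduces the *statistical skeleton* the analysis relies
on: i.i.d.-normal summer temperatures (no autocorrelation — the property
that justifies resampling temperatures at all), a log-linear $\Delta T$
response with residual scatter (`residual_sd = 0.45` log₁₀ units, chosen
so a realistic minority — roughly 1 in 5–8 — of years classify as masts),
seed pulses confined to the first quarter, and a 43-year annual record
containing a 25-year, 100-session quarterly record started at 1.0 C/100TN,
observed under multiplicative lognormal noise with unit median (default CV
0.1). The temperature mean/SD defaults (16.4 °C, 0.7 °C) are synthetic
stand-ins, not station estimates.

It does **not** emulate trap saturation and its correction (observations
are the model state times noise, not kill-trap counts), within-year
variation in breeding-season onset, spatial structure, or predators of
mice. Passing tests therefore demonstrate internal correctness and
recoverability under the stated observation model — not that the model is
adequate for any particular field record.

## Problem sizes used by the test-suite

The study-scale data conditions (43-year annual record, 100 quarterly
observations, 10% observation noise, ≥50 bootstrap replicates, 1000-year
outbreak horizon) are kept throughout. Where tests exercise the optimiser
many times (bootstrap coverage over 20 generator seeds), they reduce the
*numerical* budget only — fewer multi-starts and a $dt = 1/100$ step whose
convergence the suite itself verifies — which changes runtime, not the
statistical question.

## Known limitations

* The full (feedback, free-$\alpha$) structure is provided for the
  instability demonstration, not for inference.
* `mean_gap` between masts is the mean difference of successive mast-year
  indices; with every year flagged it is 1 by construction.
* The logistic fitter is least-squares, not likelihood-based; its AICc
  shares the RMSE convention above.
* Scenario handling is annual-series-in, annual-series-out: no downscaling
  or gridded-climate processing.
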