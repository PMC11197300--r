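---
title: "Modelling fruit-tree flowering onset from citizen-science records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fruit-tree flowering onset from citizen-science records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomwatch)
```

## The problem

Temperate fruit trees (apple, pear, cherry, plum) flower after a two-phase
winter: a *chilling* period of cool temperatures releases bud dormancy, and a
subsequent *forcing* period of warmth drives buds to bloom. Predicting the
flowering onset date for a given cultivar and place matters for frost
protection, pest and disease treatment timing, and the deployment of managed
pollinators. Long phenology series exist only for a handful of collection
orchards, so they cannot resolve how flowering varies across a country.
Opportunistic citizen-science submissions can — hundreds of dated,
georeferenced stage observations in a single spring — but they arrive noisy:
missing photographs, misjudged stages, publicity-driven bursts of submissions
and the occasional grossly wrong date.

`bloomwatch` implements the full chain from raw submissions to a national
flowering map: record cleaning, aggregation onto a 0.1° temperature grid,
daily-to-hourly temperature downscaling, a kinetic chill/heat bloom model,
simulated-annealing calibration with residual-bootstrap uncertainty,
latitudinal trend tests, and spatial prediction. A seeded synthetic-data
generator stands in for gridded weather and submissions so every stage is
testable offline against known ground truth.

## The bloom model

The model runs on hourly temperatures from a season start (default 1 August
of the preceding year, covering autumn dormancy onset through a British
spring) and tracks three state variables.

**Chill.** The dynamic model treats dormancy release as a two-step chemical
kinetic: an intermediate precursor $x$ (the precursor to the
dormancy-breaking factor, PDBF) relaxes each hour towards a
temperature-dependent steady state

$$x_s(T) = \frac{A_0}{A_1} e^{-(E_0 - E_1)/T_K}, \qquad
  k_1(T) = A_1 e^{-E_1/T_K}, \qquad
  x^* = x_s - (x_s - x)e^{-k_1},$$

with $T_K$ the temperature in Kelvin and $E_0, E_1$ activation energies
divided by the gas constant (hence in Kelvin). When the intermediate
completes ($x^* \ge 1$) a sigmoidal fraction
$\sigma(T) = 1/(1 + e^{-\mathrm{slope}\,(T - T_f)})$ converts irreversibly
into a *chill portion*; the accumulated portions are $y$. The interplay of
$x_s$ (decreasing in $T$) and $\sigma$ (increasing in $T$) produces the
characteristic band-pass chill response: nothing below a few degrees, a peak
near 7–8 °C, nothing above about 11–12 °C. With the fitted parameter sets
bundled in `example_cultivar_params()` the 1200-hour constant-temperature
response peaks between 6.8 and 8.1 °C across the four cultivars:

```{r chill-optima}
sapply(example_cultivar_params(), function(p) {
  cc <- chill_response_curve(p)
  cc$temp_C[which.max(cc$chill_portions)]
})
```

**Heat.** Growing degree hours (GDH) follow a cosine response between a base
temperature $T_b$, an optimum $T_u$ (where the hourly value is $T_u - T_b$)
and a critical temperature $T_c$, zero outside $(T_b, T_c)$.

**Transition and bloom.** Hourly GDH are weighted by
$w(y) = \min\{1, e^{s_1 (y - y_c)}\}$, so heat only counts as the chill
requirement $y_c$ is approached; the weighted sum $z$ triggers bloom at the
first hour with $z \ge z_c$. The twelve parameters
(`yc, zc, s1, Tu, E0, E1, A0, A1, Tf, Tc, Tb, slope`) are those of
`phenoflex_params()`, with calibration bounds in `phenoflex_bounds()`.

The framework this model family belongs to does not have a single published
set of equations for the transition functions; the logistic $\sigma$ and the
capped-exponential $w$ used here are isolated behind `chill_step()` and
`heat_weight()` so either can be swapped without touching callers. Fitted
parameter values are therefore implementation-relative; the chill-optimum
band above is the cross-implementation sanity check.

## Hourly temperatures

Gridded observational products supply daily minima and maxima only, while the
kinetics are hourly. `daily_to_hourly()` uses an idealized diurnal curve:
daytime follows a stretched sine from `tmin` at sunrise to `tmax` at
`sunrise + (daylength + 4)/2` hours, and after sunset the temperature decays
logarithmically to the next day's minimum at the next sunrise. Sunrise and
sunset come from the CBM day-length model (`day_length()`), a standard
solar-declination formula accurate to a few minutes at British latitudes.
Hours are local civil hours without daylight-saving adjustment. Two
properties are worth knowing: on smooth series the per-day extremes are
recovered within half a degree, but when a warm front lifts the next day's
minimum above today's maximum the night segment *rises*, so hourly values are
only guaranteed to stay within the adjacent days' envelope.

## Cleaning citizen-science records

`clean_records()` applies, in order: removal of records without photographs
(stage unverifiable), removal of records dated on configured media-spike
dates (defaults to 2022-03-19, a day on which press coverage produced a burst
of submissions), removal of records with unusable images, and removal of
locations outside Great Britain (latitude 49–61° N, longitude 8.5° W–2° E).
Because adjacent stages are hard to tell apart, the five-code scale (A–E,
BBCH 60/61/65/67/69) is coarsened to Start/Full/End for quality control;
`consensus_stats()` quantifies observer agreement on both scales, and
agreement can only increase under coarsening. Finally an interquartile-range
filter drops day-of-year values outside $[Q_1 - 1.5\,\mathrm{IQR},\;
Q_3 + 1.5\,\mathrm{IQR}]$ within each cultivar-by-phase group. Quartiles use
linear interpolation between order statistics (type 7), the single quantile
convention used package-wide. The IQR stage iterates to a fixpoint — removing
an outlier shifts the quartiles — which makes cleaning idempotent; groups
with fewer than four values pass through unfiltered.

Modelling uses onset records only (stages A/B, i.e. BBCH 60/61,
`select_onset()`), averaged per 0.1° grid cell (`aggregate_by_cell()`; means
kept fractional). The calibration/validation split (`split_cal_val()`) sorts
cells south to north and labels them cyclically `v, c, c, c` starting at the
southernmost cell, so both subsets span the latitude (and therefore
temperature) range; validation size is `ceiling(n/4)`.

## Calibration

`fit_phenoflex()` minimizes calibration RMSE over a chosen free-parameter
subset inside the bounding box, using a generalized simulated-annealing
scheme: one proposal per free parameter per iteration, mixing heavy-tailed
(t, 3 df) single-coordinate and joint moves whose scale and acceptance
temperature decay exponentially; halfway through the no-improvement patience
window the walker re-anneals from the incumbent best. The run stops at
`maxit` iterations (default 1000) or after `patience` (default 250)
iterations without improvement. A restarted Nelder–Mead local search then
polishes the best point. `refine_fit()` re-runs the whole procedure from the
previous best values and stops after two consecutive runs that improve
neither RMSE nor MAE, so the reported error sequence is non-increasing.

Two numerical choices matter:

* **Sub-day predictions.** During fitting, the bloom time is interpolated
  within the crossing hour and mapped so a midday crossing corresponds to
  that day's integer day-of-year. With integer-day predictions the RMSE
  surface is piecewise constant and every local search stalls on plateaus;
  the continuous objective removes the plateaus and the half-day alignment
  removes the systematic offset against integer observed dates.
* **No-bloom penalty.** Parameter vectors under which a cell never reaches
  `zc` are scored as the observed date plus `penalty` days (default 60),
  keeping the objective finite everywhere while guaranteeing such regions
  lose to any roughly-right fit.

`bootstrap_fit()` quantifies uncertainty by residual resampling: calibration
residuals are drawn with replacement, added to the observed dates (rounded to
whole days, matching the daily resolution of records) and the fit is re-run;
ten replicates are the convention, and per-parameter spread is reported as
the standard deviation and the 16th/84th percentiles of the replicate
distribution. `evaluate_fit()` scores held-out cells, with per-point error
bars from the replicate predictions when an ensemble is supplied.

**Identifiability.** A single season of spatial contrast identifies the chill
requirement `yc` sharply but leaves a long, nearly flat valley trading the
heat requirement `zc` against the GDH response shape (`Tu`, `Tb`): scaling
the response and the threshold together changes bloom dates very little when
spring temperatures sample only part of the response curve. In synthetic
recovery experiments the fitted `zc` can sit 15–18% from the truth for
unlucky noise draws even when the optimizer has found the global minimum.
Forward *predictions* are insensitive to position along this valley — which
is why prediction RMSE, not parameter error, is the headline metric — but
fitted parameter values should not be over-interpreted physiologically.

## Trends and spatial prediction

`fit_latitude_trend()` regresses per-cell mean onset day on latitude by OLS,
one model per cultivar, and `latitude_trend_table()` applies a
Benjamini–Hochberg correction (q = 0.05) across cultivars. `predict_grid()`
runs the fitted model over every orchard-containing cell, attaches replicate
spread when a bootstrap ensemble is supplied, flags no-bloom cells, and
classifies predictions into map classes with Jenks natural breaks
(`jenks_breaks()`, an exact Fisher dynamic program; k = 5 by default — the
choice is cosmetic and the class count is not claimed from data).
`onset_period()` summarizes the central flowering window as the 25th–75th
percentile of predicted days, and `compare_reference()` reports the mean
signed difference against a standardized long-term reference series such as a
national fruit collection's records.

## The synthetic-data generator

`gen_daily_temps()` emulates the structure of a British gridded temperature
extract: daily mean
$\mathrm{base} + \mathrm{lapse}\,(\phi - \phi_0) + A\cos(2\pi(d -
d_{\max})/365.25)$ plus per-cell AR(1) noise, split into `tmin`/`tmax` by a
fixed diurnal range. The defaults (10 °C at 51° N, −0.5 °C per degree
latitude, seasonal half-range 5.5 °C, warmest day 200, diurnal range 7 °C,
AR(1) 0.7 with 1.2 °C innovations) give maritime-temperate winters of
roughly 1–6 °C and springs that bloom the 'Victoria' reference parameters
between mid-February (50° N) and mid-April (58° N). `gen_truth()` produces
ground-truth onset days by running the forward model; `gen_records()` then
emulates submissions: stage codes sampled from a configurable distribution,
onset-stage dates at truth plus rounded Gaussian noise, later stages shifted
into +5–9 and +11–17 day windows, configurable fractions of photo-less
records and of gross outliers (±60 days by default). Everything is
deterministic given the config seeds.

What the generator does *not* emulate: spatially coherent weather systems
(noise is independent across cells), elevation and coastal effects, urban
heat islands, observer effort gradients, and weekend submission pulses.
Passing recovery tests on this generator therefore demonstrates the
correctness of the pipeline's logic under the stated noise model, not the
field performance of the calibrated parameters on real records.

## Problem sizes used in the test suite

The recovery experiment in the acceptance tests uses 100 cells across
50–58° N, three records per blooming cell with 1-day onset noise, free
parameters (`yc`, `zc`, `Tu`, `Tb`) from the conventional wide starting
values, an annealing budget of 200 iterations with patience 50, plus
refinement — about a minute of compute. The committed run recovers `yc`
within 0.2% and `zc` within 2%, with forward-prediction RMSE of 0.41 days
against truth. Oracle-equivalence tests run the engine against a literal
hour-loop re-implementation on 100 random parameter draws, the IQR filter
against brute-force fences, the Jenks program against exhaustive partition
enumeration, and the BH adjustment against hand-computed step-up values.

## Known limitations

* Parameter estimates are implementation-relative (transition-function
  conventions) and `zc`/`Tu`/`Tb` are weakly identified from one season of
  spatial contrast (see above).
* The diurnal curve is idealized; no daylight-saving, elevation, or coastal
  adjustment is made.
* The cleaning rules encode the study design of a single-country,
  single-season campaign (GB bounding box, one media-spike date); both are
  configurable but the defaults are specific.
* Chill portions keep accumulating after `yc` is reached; this is
  inconsequential for bloom (the transition weight is already 1) but means
  reported final `y` values are not capped at `yc`.
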