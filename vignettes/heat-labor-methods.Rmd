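---
title: "Methods: heat exposure, labor loss, and workshift adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat exposure, labor loss, and workshift adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatshift)
```

## The problem

Outdoor heavy labor — agriculture, forestry, fishing, construction, work at
roughly 400 W intensity — becomes progressively harder and less safe as heat
and humidity rise. One proposed adaptation is to move work from midday to
cooler hours of the day. `heatshift` quantifies (i) how many work hours are
lost to heat exposure in a 12-h workday, (ii) how much of that loss could be
recovered by shifting work to cooler hours, and (iii) how both quantities
change as the globe warms.

## Heat exposure metric

Heat exposure is measured with the simplified Wet Bulb Globe Temperature
(sWBGT), a shade/indoor index combining temperature and humidity. Two
variants are supported, matching the two kinds of input data the pipeline is
designed for:

* **hourly, reanalysis-style**: sWBGT = 0.7 Tw + 0.3 Ta, where Tw is the
  isobaric wet-bulb temperature computed from air temperature, dew point,
  and surface pressure;
* **daily, model-style**: sWBGT = 0.567 T + 0.393 VP + 3.94, where VP is the
  vapor pressure derived from specific humidity and surface pressure.

Because shade sWBGT ignores solar radiation, full-sun exposure can be 2–3 °C
higher; losses computed from it are conservative.

### The wet-bulb solver

The isobaric wet-bulb temperature is the root of the psychrometric balance

$$e_s(T_w) - e(T_d) = \gamma\, p\, (T_a - T_w), \qquad
  \gamma = 6.6\times10^{-4}\ \mathrm{^\circ C^{-1}},$$

with a Magnus-form saturation curve
$e_s(T) = 6.112\, \exp(17.67\,T/(T+243.5))$ hPa. The left side is strictly
increasing in $T_w$ and the right side strictly decreasing, so the root is
bracketed by $[T_d, T_a]$ and unique. We solve by safeguarded Newton
iteration (bisection fallback whenever a Newton step leaves the live
bracket) to a tolerance of $10^{-3}$ °C. The test suite pins the solver
against an independent plain-bisection oracle on $10^4$ random draws
(agreement within 0.01 °C). Different published wet-bulb formulations can
differ by O(0.1 °C); this choice is deterministic and oracle-verifiable.

Surface pressure for the vapor-pressure identity is reduced from sea-level
pressure with a single-layer hypsometric factor
$p_{sfc} = p_{sl}\exp(-g\,z/(R_d T_K))$, the simplest defensible reduction;
it is isolated behind one function (`surface_pressure()`) so an alternative
can be swapped in.

All temperatures are °C internally and pressures hPa; Kelvin- and
Pascal-looking inputs are detected on read (median above 150 K / 10 000 Pa)
and converted with a warning.

## Exposure-response function

The fraction of a work hour lost at a given sWBGT is a cumulative normal:

$$L(s) = \Phi\!\left(\frac{s - \mu}{\sigma}\right),
  \qquad \mu = 32.47\ \mathrm{^\circ C},\ \sigma = 4.16\ \mathrm{^\circ C}
  \ \text{(heavy work)}.$$

The printed form of this response is typographically ambiguous about
parenthesization; we resolve it as the standard normal CDF of the
standardized sWBGT, which reproduces the established anchors: ~50% loss at
32.5 °C, ~10% at 27 °C, ~90% at 38 °C, under 1% at 20 °C.

The smooth function is used everywhere; no 10%/90% clipping is applied by
default. The conventional cutoff variant (losses below 10% set to zero,
capped at 90%) is available via `clip = TRUE` for comparison with older
analyses. Parameters for lighter work intensities can be supplied through
`erf_params()`, but heavy work is the shipped default since it dominates
heat-related losses.

## Workday accounting

Losses are accounted per local solar day (midnight-to-midnight windows after
shifting each cell's series by `round(lon/15)` hours; the shift is circular
at the series edges, blurring at most half a day at each end of a multi-year
series). Within each day:

* **full12** — the 4+4+4 method: the 12-h workday is 4 h at the daily
  maximum sWBGT, 4 h at the daily mean, and 4 h at their midpoint, so
  $\text{loss} = 4[L(\max) + L(\text{mean}) + L(\tfrac{\max+\text{mean}}{2})]$
  hours. This uses the day's mean/max, not clock hours, and saturates at
  12 h/day (4380 h/person/year over a 365-day year).
* **ranked hour classes** — the 24 hourly values are ordered coolest to
  hottest (stable sort, ties broken by earlier hour). `hottest1`/`coolest1`
  are the extreme hours, `morning1` is the *third-coolest* hour (a
  realistic early-morning work start, typically near sunrise), and the
  3- and 12-hour classes take the corresponding ranked blocks. Each
  saturates at its class size × days per year (365 h/year for single-hour
  classes).

Ranking is done per calendar day on the hourly series, not on monthly
climatologies: the per-day choice matches how a worker would actually
experience and avoid the day's heat. Leap days are included when the
calendar contains them; ceilings use actual day counts.

## Pattern scaling

Future heat exposure is projected by *pattern scaling*: local monthly
warming per degree of global warming, estimated from a model ensemble and
applied additively to the hourly baseline.

Per model: the annual global-mean (cosine-latitude-weighted) temperature
and the local monthly sWBGT series are smoothed with a 20-year lowpass
filter, converted to anomalies from their first smoothed value, and an
ordinary least-squares slope is fitted per (cell, month). The lowpass is a
centered 21-point running mean with half weights on the two end points
(total weight 20 years) — the standard even-length centered moving average.
We chose this form because it leaves a linear trend unchanged in the
interior, which a one-sided-centered 20-point mean would not; windows are
truncated and renormalized at the edges. Anomalies versus absolute values do
not affect the slope, only the (unused) intercept.

Across models we take the element-wise **median** (local warming slopes are
not normally distributed across ensembles, so the median is more robust
than the mean) and flag cells where the inter-model coefficient of
variation — standard deviation divided by the absolute median — exceeds
0.35 as non-robust. Cells whose median slope is within $10^{-3}$ of zero
report an infinite CV and are non-robust; such cells are climatically
negligible and the guard avoids division blowup. We use sd/|median| rather
than sd/median so that a negative-median cell cannot masquerade as robust.

Application is additive and month-specific: at global warming `dT`, every
hour in month *m* at cell *c* is shifted by `dT × slope[c, m]`. The whole
diurnal cycle shifts uniformly — ensembles do not agree on the sign of
max-vs-min differences in warming, and their magnitude is small. Warming
levels are defined relative to the baseline period mean. Patterns estimated
on a coarser model grid are brought to the baseline grid by bilinear
interpolation (`regrid_pattern()`), with nearest-edge clamping outside the
source hull.

## Population, labor, and economic weighting

Gridded per-person losses (hours/person/year) are regridded bilinearly to
the population grid, multiplied by the gridded heavy-labor worker count
(working-age population × the country's heavy-labor fraction — workers are
assumed to be distributed like the general population, as sub-national
labor data are rarely available), and summed within country borders. Global
totals are sums over countries, so conservation is exact by construction.
Economic losses multiply hours lost by each country's hourly output,
defined as annual output per worker divided by 4380 (12 h/day × 365 days),
consistent with the workday accounting. Population and earnings are held
static across warming levels — a conservative choice, since populations in
the most-affected regions are projected to grow.

## Adaptation metrics

* `recoverable_percent(hot, cool)` = 100 (hot − cool)/hot: the share of the
  hot-class loss avoided by working the cool class instead. Single-hour
  swaps use the hottest-hour loss as the denominator.
* `shift_recovery()` expresses a class swap as a percent of the **full
  12-h workday** loss — used for the 3-hottest → 3-coolest swap. The two
  denominators serve different questions (how much of the midday loss is
  avoidable, versus how much of the whole day's loss).
* For a morning-hour swap at a warming level, the denominator is the
  hottest-hour loss at the *same* level, so the metric reflects the
  contemporaneous trade-off.

A provable property of the normal CDF (its reverse hazard rate
$\phi/\Phi$ is decreasing) is that under a uniform positive shift applied
to any diurnal cycle with coolest < hottest sWBGT, the ratio
$L(\text{cool}+\Delta)/L(\text{hot}+\Delta)$ rises with $\Delta$, so the
recoverable percent strictly falls as the climate warms. The test suite
verifies this on 100 random diurnal cycles.

Losses-per-degree slopes are ordinary least-squares fits of annual global
loss sums on annual global temperature anomalies; uncertainty is reported
as the OLS standard error (stated explicitly, since "±" conventions vary).
To estimate the slope at a warming level, the pattern at that fixed level
is added to every year of the baseline before regressing, so the slope
reflects interannual variability around the warmer mean state.

## The synthetic world

The generator produces inputs with the statistical structure the analysis
assumes, so every stage is testable without archives of reanalysis, model,
or population data:

* **hourly climate** — `base(lat) + seasonal + diurnal + annual anomaly +
  AR(1) noise`. Defaults (chosen once, as a realistic tropical–subtropical
  testbed, and not revisited): a 6 × 8 grid spanning ±35° latitude;
  equatorial baseline 29 °C falling quadratically with latitude
  (−14 °C at 45°); diurnal amplitude 3.5 °C peaking at 14:00 local solar
  time with the minimum near sunrise; seasonal amplitude 4 °C peaking
  mid-July north of the equator and mid-January south; hourly AR(1) noise
  with marginal sd 1 °C and coefficient 0.7; a shared annual anomaly with
  sd 0.3 °C emulating interannual variability. These place the bulk of the
  domain on the rising limb of the exposure-response curve, where the
  adaptation question is live.
* **model ensemble** — each member has a global trajectory warming ~3 °C
  over 60 years plus AR(1) variability, and local monthly sWBGT equal to a
  known true slope times the global series plus AR(1) noise (sd 0.3 °C).
  True slopes are the monthly values 0.8–1.5 °C/°C modulated by latitude
  (low-latitude amplification up to 15%) and are recorded for recovery
  tests. Noise is independent across cells — the simplest structure that
  exercises the lowpass and regression stages.
* **country fixture** — contiguous country blocks, log-uniform cell
  populations (10³–10⁶), heavy-labor fractions in [0.05, 0.6], and annual
  output per worker spanning roughly 3 000–100 000 PPP$ (low- to
  high-income).

What the generator does **not** emulate: spatial covariance of real
reanalysis fields, explicit humidity physics (it generates sWBGT directly
for the accounting stages), real country geometries, and urban/rural
population structure. Passing tests therefore demonstrate the correctness
of the accounting, scaling, and aggregation machinery — not the realism of
any particular climate. Real-data runs plug into the same functions through
the gridded readers.

In slope regressions on the synthetic world, the annual global-mean sWBGT
anomaly stands in for the global air-temperature series (the synthetic
world carries no separate air-temperature field); the steepening property
being tested is insensitive to this choice of covariate.

## Numerical choices and problem sizes

* Wet-bulb tolerance $10^{-3}$ °C; solver errors out with the residual if
  it cannot converge rather than returning silently.
* Hour-ranking ties break by earlier local hour, making orderings stable
  and runs bit-reproducible.
* All generators require an explicit seed; run manifests record the seed,
  a configuration hash, and per-stage checksums, and re-running an
  identical configuration reproduces identical checksums.
* Test and acceptance runs use deliberately small problem sizes — grids of
  2 × 2 to 6 × 8 cells, 1–6 years of hourly data, ensembles of 3–5 members
  × 40–60 years, 50-seed replications for bias checks. The pipeline is
  O(cells × hours) throughout, so these sizes exercise every code path
  while keeping the full suite around ten seconds.

## Known limitations

* Shade sWBGT underestimates full-sun exposure, and reanalysis-style
  inputs underestimate station extremes; losses are conservative.
* The 4+4+4 workday is an approximation to hour-by-hour accounting within
  the 12-h workday; it is retained for comparability with established
  estimates.
* The heavy-labor aggregate is a single sector bundle; no sub-national
  labor distribution, sectoral split, or daylight constraint on shifted
  hours is modelled.
* Pattern scaling assumes local monthly sWBGT responds linearly to global
  temperature with a fixed spatial pattern; interannual variance is not
  rescaled under warming.
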