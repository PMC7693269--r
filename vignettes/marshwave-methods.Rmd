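---
title: "Methods: salt-marsh phenology and shorebird annual-cycle timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-marsh phenology and shorebird annual-cycle timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshwave)
```

## The scientific problem

Migratory shorebirds that breed in Atlantic salt marsh face a latitudinal
gradient in habitat phenology: the dominant marsh grass (*Spartina*-type
cordgrass) greens up weeks later in Maine than in Georgia. If breeding is
timed to a fixed *stage* of local marsh green-up — a "green wave" — then
birds breeding further north should be later at every stage of their
annual cycle, by the same latitudinal pace that the vegetation itself
shows. Testing this requires three independent measurement chains:

1. a **thermal indicator** of spring: growing degree days accumulated
   above the 10 °C threshold for cordgrass growth, and the spring peak of
   the third time-derivative of that accumulation (the degree-day "jerk",
   a standard onset-of-spring proxy);
2. a **vegetation indicator**: multi-study seasonal biomass measurements,
   standardized to fraction of seasonal maximum and modelled as a linear
   function of date, latitude and their interaction;
3. **bird timing**: light-level geolocator records classified into
   twilight times, positions, sustained transoceanic flights, incubation
   bouts and finally a per-individual annual-cycle event table.

marshwave implements all three chains plus the estimators that connect
them, and — because real station records, digitized biomass tables and
raw tag data cannot be bundled — a synthetic-data module that generates
all four input streams from known ground truth, so that every stage of
the analysis can be tested end to end.

## The synthetic world and what it does (and does not) emulate

The generators are plain parametric models with documented defaults, and
the defaults *are* the study conditions used by the test suite.

**Climate** (`climate_params()`, `sim_climate()`). Daily mean temperature
is a cosine of day of year with a linear latitudinal offset:
12.5 °C annual mean at the 39.2°N reference, −0.9 °C per degree
northward, ±12 °C seasonal swing peaking on day 200, an 8 °C diurnal
range and i.i.d. N(0, 2²) daily noise. Years are 365 days; leap days are
never generated (and `doy_from_time()` collapses Feb 29 when ingesting
real dates), so climatologies align exactly. This captures the
first-order structure a degree-day analysis consumes — it does not
emulate synoptic autocorrelation, coastal microclimate or the asymmetric
(lagged) shape of real marine-influenced springs, which is why the
synthetic thermal spring runs ~3 weeks earlier than the real mid-Atlantic
coast. Scripted bird schedules are therefore anchored to the synthetic
wave, not to published calendar dates.

**Biomass** (`biomass_params()`, `sim_biomass_studies()`). Eight studies
at latitudes 31.3–45.3° observe a logistic green-up
\(B(d) = B_{max}/(1+e^{-r(d-m(lat))})\) with rate \(r = 0.05\,d^{-1}\)
(10–90 % green-up in ~90 days). The midpoint is **coupled to the
climate**: \(m(lat) = 111 + 3.55\,(lat - 39.2)\), i.e. about 17 days
after the thermal spring onset of the default climate and advancing at
the same 3.55 d/° pace — the two indicators express one wave, as in the
real system. Each study harvests 20 replicate plots (cv 15 %) every ten
days from early February to early September; reported means, SEs and n
mimic what a meta-analysis can extract from published tables. Seasonal
maxima differ 2.7-fold across studies so the standardization step is
genuinely exercised.

**Tracks** (`track_script()`, `sim_geolocator_track()`). A scripted year:
wintering on the north coast of South America, a two-leg northbound
migration (a ~4-day transoceanic flight, a stopover on the southeast US
coast, a ≥24 h final leg), breeding, daily midday incubation bouts from
nest initiation, and a mirrored southbound migration. Light follows NOAA
solar elevation at the (moving, great-circle) position — zero below −6°
sun elevation, full scale above 0°, linear between; incubation forces
daytime light to zero. Conductivity is wet with probability 0.8 in
daylight and 0.5 at night when stationary (arbitrary but fixed texture)
and continuously dry in flight, with the samples bounding each flight
wet — a marsh bird is in the water up to departure — which pins detected
flight boundaries to the script within one sampling interval (5 min
default). The generator does **not** model weather shading, sensor noise
or equinox-latitude error; passing recovery tests therefore demonstrate
the classification logic, not robustness to every field artefact.

**Observation frequencies** (`obs_ramp_params()`,
`sim_observation_records()`). Seven 2°-latitude bins; the expected
reporting proportion follows a logistic ramp whose centre is solved (by
bisection) so that the noise-free cumulative curve reaches 2 % of its
seasonal total exactly on the scripted arrival day; daily counts are
Poisson around effort × proportion, for ten independent years.

## Degree days, the jerk, and smoothing

`daily_gdd()` implements the single-sine method with the three classical
interception cases (all-above, all-below, intercepted); the intercepted
case integrates the sine above the base in closed form, and the suite
checks it against blind numerical quadrature. `cumulative_gdd()` sums
within calendar years (gaps ≤ 3 days are linearly interpolated, longer
gaps error), and `average_climatology()` takes the pointwise multi-year
mean.

The onset statistic is the spring argmax (window: days 1–181, excluding
autumn deceleration) of the third central finite difference of the
smoothed climatology. Smoothing is the load-bearing numerical choice
here: a third difference amplifies high-frequency noise so strongly that
a *single* centred moving average of any width leaves the statistic
noise-dominated — the third difference of a box-smoothed noise series is
dominated by the kernel's sharp edges. `gdd_jerk()` therefore iterates
the moving average (`passes = 3`, halfwidth 15 by default; the pipeline
uses halfwidth 20), giving a quasi-Gaussian composite kernel with enough
smoothness that the differentiated noise collapses while the seasonal
signal (period ~365 d) is attenuated by only a few percent. With this
choice the onset is exactly monotone in latitude on the noise-free grid
and stable to ±2 days under 30-year averaging of noisy climates; with a
single pass it is meaningless. The smoothing applied by the web tools
that popularized the jerk statistic is undocumented, so these are
declared parameters of *this* implementation, not claims about anyone
else's.

Two exact properties anchor the tests: translating the input temperature
series by k days translates the onset by exactly k, and the third
central difference is exact for cubic polynomials.

## Geolocator event classification

`detect_twilights()` finds linearly interpolated threshold crossings
(default threshold 1), with one deliberate refinement: a crossing only
counts as a twilight if it bounds a dark period of at least 4 h. Without
this gate, midday incubation shading generates spurious "sunset/sunrise"
pairs that outnumber the real ones during persistent incubation, and the
35-minute median-deviation outlier filter (`filter_twilight_outliers()`,
±2-day neighbourhood, applied twice) then removes the *true* events.
Setting `min_dark_hours = 0` recovers the unconditional behaviour.

`threshold_positions()` converts rise/set pairs to positions: longitude
from equation-of-time-corrected local apparent noon (15°/h), latitude by
solving the sunrise equation for the observed day length at the
configured zenith (default 96°, matching the generator's −6° night
angle). Of the two geometric roots, the hemisphere is chosen by whether
the day is longer or shorter than the equinoctial day for that zenith.
Latitude is left undefined within 10 min of a 12 h day and
`mask_equinox()` additionally suppresses latitudes within ±40 days of
the equinoxes; longitudes are kept, and event timing uses longitudes and
conductivity only, so equinoxes do not move event dates.

`classify_flights()` returns maximal dry runs ≥ 20 h (configurable; the
generator's sedentary dry spells are sub-hour, transoceanic legs are
multi-day, so the threshold sits in a wide indifference zone).
`detect_incubation()` calls a bout a ≥1 h dark run strictly between a
rise and the following set, and requires three consecutive bout-days to
declare nest initiation, so a single shading artefact cannot define it.
`build_event_table()` groups flights separated by < 30 days into one
migration (stopovers), assigns direction by comparing stationary
longitudes before/after each migration with the breeding-site longitude,
and derives the five events and their duration identities
(durations are exact differences of bounding events; wintering wraps the
year).

## The green-wave model

`standardize_biomass()` rescales each study by its seasonal maximum of
mean standing biomass — "total seasonal biomass" is not defined more
precisely in the sources this mirrors, and the maximum makes the stage a
bounded green-up fraction; values slightly above 1 under noise are kept,
not clipped, to avoid truncation bias. Weights are inverse variances of
the standardized stages.

`fit_greenwave()` estimates
\(stage = \beta_0 + \beta_d\,doy + \beta_l\,lat + \beta_{dl}\,doy\cdot
lat\) (identity link, fraction scale) by generalized estimating
equations: block-diagonal AR(1) working correlation within studies (by
visit order — calendar spacing is close to uniform in the default
world), observation-level inverse-variance weights, iterating weighted
GLS with moment re-estimation of ρ from lag-1 standardized residuals
(denominator \(N^* - p\)) until coefficients move < 1e-8; covariates
are centred internally for conditioning and mapped back exactly. With
ρ = 0 the fit reduces to weighted least squares to machine precision.
Both sandwich (default) and model-based standard errors are kept: in
simulations *from* the working model the model-based covariance is
exact and 2-SE intervals cover at ~95 %, whereas the sandwich estimator
with only 8 clusters under-covers (~80 %) — a well-known small-sample
property, which is why the parameter-recovery tests use model-based SEs
and real-data inference should prefer the sandwich values with that
caveat in mind.

`predict_stage()` / `stage_date()` are exact inverses on the fitted
linear form. `stage_at_events()` predicts each bird's stage at its nest
date and tests across-site homogeneity with a Kruskal–Wallis rank test
(degenerate all-equal input returns statistic 0, p 1).

A linear surface is deliberately fitted to a logistic truth, so the
model is misspecified by construction — as any date × latitude linear
model of a saturating green-up must be. Two consequences are documented
rather than hidden. First, the fit is restricted to the early green-up
limb (stages 0.10–0.50 in the pipeline): on that limb the logistic is
near-linear and the inversion bias of `stage_date()` stays below a day.
Second, the *absolute* scripted stage (0.295) is recovered only up to a
small systematic offset (the fitted common stage is a model-scale
quantity); what the pipeline recovers sharply is that the stage is
*common across sites* (each site within ±0.01 of the common value) and
that inverting it reproduces the nest dates on the 1:1 line within a
day. The published target of 29.5 % was itself derived from data as the
mean predicted stage at nest initiation, and `run_config()` mirrors
exactly that: `target_stage = NULL` means "use the data-derived mean".

## Timing inference

`fit_site_timing()` is a random-intercept model
(`doy = site + (1|individual) + error`) fitted by REML with the
individual-to-residual variance ratio profiled out and optimized by
bounded scalar search (log-ratio in [−12, 12], tolerance 1e-10, with an
explicit check of the zero-variance boundary). Marginal means are the
site fixed effects under cell-means coding. The suite requires agreement
with an independent mixed-model implementation (lme4) to 1e-6 on both
means and standard errors. Whether the original analyses used ML or
REML is unstated in the sources this mirrors; REML is the conventional
choice for variance components and is what is implemented.

`latitude_regression()` and `slope_homogeneity()` are ordinary least
squares on site-level marginal means (the latter reporting the
category × latitude interaction). `tail_align_estimate()` estimates a
poorly-sampled site's mean from its earliest reported date plus the
reference sample's mean-minus-minimum (the "left tail" is the sample
minimum by default; a fitted-normal 2.5th percentile is available — the
minimum is used because the reference samples here are small, n ≈ 20,
where an order statistic is a steadier anchor than a tail quantile of a
fitted distribution). `arrival_from_observations()` applies the
cumulative-2 % rule with ≥ (first qualifying day), per year, then
averages years and reports the between-year SE.

`maxstat_cutpoint()` searches all midpoints between sorted unique
covariate values that leave at least `min_prop` (default 0.1) of the
data on each side, computes the standardized sum statistic
\(T(c) = |S_c - E S_c| / \sqrt{\mathrm{Var}\,S_c}\) under permutation
moments, and takes the maximum (ties to the smaller cutpoint). Its
p-value is a seeded permutation test with plus-one correction — exact at
small n and uniform on the null by construction, verified by a
Kolmogorov–Smirnov check over 500 null simulations; the asymptotic
improved-Bonferroni approximation used by some implementations is out of
scope. The brute-force enumeration oracle in the tests must agree
exactly at n = 12.

## The pipeline

`run_greenwave_pipeline(run_config(seed))` runs everything: onset over a
32–44° station grid, the green-wave fit, scripted tracks per site
(defaults: 7 + 6 + 7 birds at the New Jersey / southern Massachusetts /
northern Massachusetts–Maine latitudes, nests scripted at the day their
latitude reaches 29.5 % of seasonal biomass, ±1 day of individual
jitter), full event detection per track, site-level marginal means, the
stage-at-nest summary, the per-site nest-vs-indicator table (the 1:1
check), the per-latitude indicator-vs-indicator table with regression
and cutpoint analysis, and a manifest (config hash, seed, sizes). Every
random draw descends from the single config seed; two runs with the same
config are identical. Any stage failure aborts with the stage's name.

Problem sizes are chosen to exercise the analysis at the scale it is
meant for: 13 stations, 8 studies × 22 visits, 20 tracks of a full year
at 5-minute sampling, 200-replicate parameter-recovery simulations, 100
step-recovery simulations and 500 null-calibration simulations for the
cutpoint machinery.

## Known limitations

* The climate is a noise-dressed cosine; onset values are internally
  consistent but ~3 weeks earlier than the real mid-Atlantic coast, and
  no claim is made about reproducing published station-level onset dates
  or the published multi-decade onset shift (those depend on real
  station records).
* The green-wave model's printed real-data coefficients are not
  reproducible without the underlying digitized study tables; the model
  is validated by simulation (known-truth recovery and exact reductions)
  instead.
* Threshold positioning is a deliberate simplification of full
  tag-calibration + MCMC pipelines; it is accurate to ~0.5° longitude
  and ~2° latitude away from the equinoxes on clean synthetic light, and
  is used here only to orient migrations.
* The permutation maxstat treats observations as exchangeable; spatially
  autocorrelated deviations would make its p-value anti-conservative.
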