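# marshwave

Tools for testing whether a migratory shorebird's annual cycle tracks a
latitudinal **green wave** of salt-marsh phenology. Written for movement
ecologists and phenology modellers working with the east-coast
salt-marsh system (breeding *Tringa*-type shorebirds, *Spartina*-
dominated marsh), but every component is generic: degree-day
climatologies, light-level geolocator classification, multi-study
biomass standardization and the timing estimators are reusable on any
comparable system.

The package implements three measurement chains and the statistics that
connect them:

* **Thermal spring onset.** Single-sine growing degree days above a base
  temperature (default 10 °C, the *Spartina* growth threshold), averaged
  into multi-year climatologies; the spring onset statistic is the
  spring maximum of the **degree-day jerk** — the third time-derivative
  d³(cumGDD)/dt³ of the smoothed cumulative curve, whose early-spring
  peak is a standard "onset of spring" proxy
  (`daily_gdd()`, `cumulative_gdd()`, `average_climatology()`,
  `gdd_jerk()`, `spring_onset()`, `onset_shift()`).
* **Vegetation green-up.** Multi-study seasonal biomass standardized to
  *phenological stage* (fraction of within-study seasonal maximum), then
  an inverse-variance weighted GEE with AR(1) working correlation for
  `stage = β₀ + β_d·doy + β_l·lat + β_dl·doy·lat`, with robust and
  model-based SEs, closed-form inversion for the date a target stage is
  reached, and per-site stage-at-nest summaries
  (`standardize_biomass()`, `fit_greenwave()`, `predict_stage()`,
  `stage_date()`, `stage_at_events()`).
* **Bird timing.** Geolocator light and wet/dry conductivity series
  classified into twilights (threshold crossings with outlier editing),
  threshold positions with equinox masking, sustained dry-spell flights,
  daytime-darkness incubation bouts, and a per-individual annual-cycle
  event table; site-level marginal means come from a REML
  random-intercept model, plus latitude regressions, tail-alignment and
  cumulative-2 % arrival estimators, and a permutation-based maximally
  selected cutpoint statistic
  (`detect_twilights()`, `classify_flights()`, `detect_incubation()`,
  `build_event_table()`, `fit_site_timing()`, `maxstat_cutpoint()`, ...).

A first-class synthetic-data module (`sim_climate()`,
`sim_biomass_studies()`, `sim_geolocator_track()`,
`sim_observation_records()`) generates all four input streams from known
ground truth, and `run_greenwave_pipeline()` runs the whole analysis end
to end on simulated or user-supplied tables. All user-facing functions
take data frames and return tibbles; fitted objects have `tidy()` /
`glance()` methods and `autoplot()` figures.

## Worked example

Published site-level timing tables can be summarized directly. The
bundled table of marginal mean event dates for three breeding-site
groups (New Jersey 39.2°N, southern Massachusetts 41.4°N, northern
Massachusetts/Maine 43.0°N) gives the average northern-versus-southern
timing offset:

```r
library(marshwave)
tab <- willet_timing_table()
timing_difference_summary(tab)$mean_offset_days
#> [1] 15.46
```

— all five annual-cycle stages run on average about 15 days later for
the northern site groups.

Fitting the green-wave model to simulated biomass studies (eight
studies, Georgia to Nova Scotia, standardized to stage and restricted to
the early green-up limb):

```r
set.seed(1)
std <- standardize_biomass(sim_biomass_studies(biomass_params(seed = 1)))
fit <- fit_greenwave(dplyr::filter(std, stage >= 0.1, stage <= 0.5))
tidy(fit)
#> # A tibble: 4 × 5
#>   term           estimate std.error statistic  p.value
#>   <chr>             <dbl>     <dbl>     <dbl>    <dbl>
#> 1 intercept     0.722     0.0687        10.5  7.63e-26
#> 2 doy           0.00672   0.000615      10.9  9.09e-28
#> 3 latitude     -0.0297    0.00228      -13.0  7.72e-39
#> 4 doy_latitude  0.0000275 0.0000201      1.37 1.70e- 1

stage_date(fit, 0.295, 39.27)   # day the NJ latitude reaches 29.5 % stage
#> [1] 94.7
stage_date(fit, 0.295, 43.03)   # ~13 days later at the Maine latitude
#> [1] 107.6
```

The negative latitude coefficient with a positive date coefficient is
the green wave itself: at a fixed date, more northern marsh is at an
earlier stage, so any fixed stage is reached later in the north — here
at about 3.5 days per degree of latitude, matching the latitudinal pace
of the synthetic world's thermal spring.

The full coupled pipeline (simulate → detect → model → compare):

```r
res <- run_greenwave_pipeline(run_config(seed = 1))
res$fig3
#> # A tibble: 3 × 5
#>   site        latitude nest_doy onset_doy stage_date_doy
#>   <chr>          <dbl>    <dbl>     <dbl>          <dbl>
#> 1 MA_north_ME     43.0    107.      107.           108.
#> 2 MA_south        41.3    101.      101.           101.
#> 3 NJ              39.3     93.9      93.8           93.7
```

Each site's detected mean nest date sits on the 1:1 line against both
phenological indicators (thermal onset and the date the common biomass
stage is reached) to within a fraction of a day, and
`res$stage_summary$by_site` shows the three sites nesting at the same
biomass stage (±0.002 here).

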