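#' Parameters for synthetic seasonal biomass studies
#'
#' Emulates a set of independent field studies, each measuring standing
#' *Spartina*-type biomass repeatedly through one growing season at its own
#' latitude. True standing biomass follows a logistic green-up curve
#'
#' \deqn{B(d) = B_{max} / (1 + e^{-r (d - m(lat))})}
#'
#' whose midpoint shifts north at `midpoint_lat_shift` days per degree of
#' latitude. Reported values are sample means of `n_reps` replicate plots
#' with multiplicative noise (`cv`), with a standard error computed from
#' the replicates. Defaults emulate eight intensive east-coast studies
#' (Georgia to Nova Scotia), each harvesting 20 replicate plots every ten
#' days from late winter through summer:
#' green-up over roughly 90 days (rate 0.05/day), with the midpoint placed
#' so the green-up wave rides the thermal spring of the default
#' [climate_params()] world (about 17 days after the degree-day spring
#' onset, advancing 3.55 days per degree of latitude) — the coupling that
#' makes biomass stage and temperature acceleration two expressions of the
#' same latitudinal wave.
#'
#' @param latitudes Study latitudes, degrees (one study per entry).
#' @param logistic_midpoint_at_ref Day-of-year at which biomass reaches half
#'   its seasonal maximum at `ref_lat`.
#' @param midpoint_lat_shift Northward delay of the midpoint, days per degree.
#' @param logistic_rate Logistic growth rate, per day (> 0).
#' @param seasonal_max Seasonal maximum biomass per study, g dry mass / m^2.
#'   Recycled across studies; heterogeneous values exercise the
#'   standardization step.
#' @param cv Coefficient of variation of replicate plots (> 0).
#' @param sampling_dates Days of year sampled, shared across studies
#'   (strictly increasing, >= 2).
#' @param n_reps Replicate plots per sampling date.
#' @param ref_lat Reference latitude, degrees.
#' @param seed Integer seed.
#' @return A `biomass_params` list.
#' @export
biomass_params <- function(latitudes = c(31.3, 33.0, 35.0, 37.8, 39.3, 41.3, 43.0, 45.3),
                           logistic_midpoint_at_ref = 111,
                           midpoint_lat_shift = 3.55,
                           logistic_rate = 0.05,
                           seasonal_max = c(1200, 1100, 900, 800, 700, 600, 500, 450),
                           cv = 0.15,
                           sampling_dates = seq(40, 250, by = 10),
                           n_reps = 20,
                           ref_lat = 39.2,
                           seed = 1L) {
  .assert(logistic_rate > 0, "logistic_rate must be > 0")
  .assert(cv >= 0, "cv must be >= 0")
  .assert(length(sampling_dates) >= 2, "need at least 2 sampling dates per study")
  .assert(all(diff(sampling_dates) > 0), "sampling dates must be strictly increasing")
  structure(
    list(
      latitudes = latitudes,
      logistic_midpoint_at_ref = logistic_midpoint_at_ref,
      midpoint_lat_shift = midpoint_lat_shift,
      logistic_rate = logistic_rate,
      seasonal_max = rep_len(seasonal_max, length(latitudes)),
      cv = cv,
      sampling_dates = sampling_dates,
      n_reps = as.integer(n_reps),
      ref_lat = ref_lat,
      seed = as.integer(seed)
    ),
    class = "biomass_params"
  )
}

#' True biomass and midpoint of the synthetic green-up curve
#'
#' Ground-truth helpers for recovery tests: the logistic curve underlying
#' [sim_biomass_studies()] and the day-of-year at which it reaches a given
#' fraction of its asymptote.
#'
#' @param params A [biomass_params()] object.
#' @param doy Day of year.
#' @param latitude Degrees.
#' @param stage Fraction of the seasonal maximum, in (0, 1).
#' @return `true_biomass()`: g/m^2; `true_stage_date()`: day of year.
#' @export
true_biomass <- function(params, doy, latitude) {
  m <- params$logistic_midpoint_at_ref +
    params$midpoint_lat_shift * (latitude - params$ref_lat)
  idx <- match(latitude, params$latitudes)
  bmax <- ifelse(is.na(idx), mean(params$seasonal_max), params$seasonal_max[idx])
  bmax / (1 + exp(-params$logistic_rate * (doy - m)))
}

#' @rdname true_biomass
#' @export
true_stage_date <- function(params, stage, latitude) {
  .assert(all(stage > 0 & stage < 1), "stage must be in (0, 1)")
  m <- params$logistic_midpoint_at_ref +
    params$midpoint_lat_shift * (latitude - params$ref_lat)
  m + log(stage / (1 - stage)) / params$logistic_rate
}

#' Simulate multi-study seasonal biomass measurements
#'
#' @param params A [biomass_params()] object.
#' @return A tibble of biomass observations: `study_id`, `latitude`, `doy`,
#'   `biomass_mean`, `biomass_se`, `n` — the common exchange format for
#'   [standardize_biomass()].
#' @export
sim_biomass_studies <- function(params) {
  .assert(inherits(params, "biomass_params"), "params must come from biomass_params()")
  p <- params
  grid <- tidyr::expand_grid(
    study = seq_along(p$latitudes),
    doy = p$sampling_dates
  )
  .with_seed(p$seed, {
    purrr::pmap_dfr(grid, function(study, doy) {
      lat <- p$latitudes[study]
      b <- true_biomass(p, doy, lat)
      reps <- b * (1 + rnorm(p$n_reps, 0, p$cv))
      reps <- pmax(reps, 0)
      tibble::tibble(
        study_id = sprintf("study_%02d", study),
        latitude = lat,
        doy = doy,
        biomass_mean = mean(reps),
        biomass_se = max(sd(reps) / sqrt(p$n_reps), 1e-6 * max(b, 1)),
        n = p$n_reps
      )
    })
  })
}
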