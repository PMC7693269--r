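#' Parameters for the synthetic coastal climate
#'
#' Describes a latitude-graded sinusoidal temperature climate for the
#' Atlantic coast of North America. Daily mean temperature at a station is
#'
#' \deqn{T(d) = T_{ref} - g (lat - lat_{ref}) + A \cos(2\pi (d - d_{peak})/365) + \epsilon}
#'
#' with \eqn{\epsilon \sim N(0, \sigma^2)} and daily min/max offset by half
#' the diurnal range. Defaults are centred on a mid-Atlantic (New Jersey)
#' reference station: 12.5 C annual mean, 0.9 C cooling per degree of
#' latitude northward, 12 C seasonal amplitude peaking in mid July.
#'
#' @param mean_annual_temp_at_ref Annual mean temperature at `ref_lat`, deg C.
#' @param lat_gradient Cooling per degree latitude northward, deg C per deg.
#' @param seasonal_amplitude Half peak-to-trough seasonal swing, deg C (>= 0).
#' @param peak_day Day of year of the warmest day.
#' @param diurnal_range Daily max minus min, deg C (>= 0).
#' @param noise_sd SD of day-to-day temperature noise, deg C.
#' @param years Number of simulated years (>= 1).
#' @param ref_lat Reference latitude, degrees.
#' @param seed Integer seed making the simulation reproducible.
#' @return A `climate_params` list.
#' @export
climate_params <- function(mean_annual_temp_at_ref = 12.5,
                           lat_gradient = 0.9,
                           seasonal_amplitude = 12,
                           peak_day = 200,
                           diurnal_range = 8,
                           noise_sd = 2,
                           years = 10,
                           ref_lat = 39.2,
                           seed = 1L) {
  .assert(seasonal_amplitude >= 0, "seasonal_amplitude must be >= 0")
  .assert(diurnal_range >= 0, "diurnal_range must be >= 0")
  .assert(years >= 1, "years must be >= 1")
  structure(
    list(
      mean_annual_temp_at_ref = mean_annual_temp_at_ref,
      lat_gradient = lat_gradient,
      seasonal_amplitude = seasonal_amplitude,
      peak_day = peak_day,
      diurnal_range = diurnal_range,
      noise_sd = noise_sd,
      years = as.integer(years),
      ref_lat = ref_lat,
      seed = as.integer(seed)
    ),
    class = "climate_params"
  )
}

#' Simulate daily station temperatures
#'
#' Generates `years` x 365 daily records (leap days are never generated, so
#' climatologies align exactly across years) for one station at the given
#' latitude, following the climate model in [climate_params()].
#'
#' @param params A [climate_params()] object.
#' @param latitude Station latitude, degrees.
#' @param station_id Station label carried through to outputs.
#' @return A tibble with columns `station_id`, `latitude`, `year`, `doy`,
#'   `tmin`, `tmax` (deg C).
#' @export
sim_climate <- function(params, latitude, station_id = "station_1") {
  .assert(inherits(params, "climate_params"), "params must come from climate_params()")
  p <- params
  n <- p$years * 365L
  doy <- rep(1:365, times = p$years)
  year <- rep(seq_len(p$years), each = 365L)
  tmean <- p$mean_annual_temp_at_ref -
    p$lat_gradient * (latitude - p$ref_lat) +
    p$seasonal_amplitude * cos(2 * pi * (doy - p$peak_day) / 365)
  if (p$noise_sd > 0) {
    noise <- .with_seed(p$seed + round(latitude * 1000), rnorm(n, 0, p$noise_sd))
    tmean <- tmean + noise
  }
  tibble::tibble(
    station_id = station_id,
    latitude = latitude,
    year = year,
    doy = doy,
    tmin = tmean - p$diurnal_range / 2,
    tmax = tmean + p$diurnal_range / 2
  )
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}
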