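#' Script the annual cycle of a tracked individual
#'
#' Defines the ground truth for one synthetic geolocator deployment: where
#' the bird is through a 365-day year (leap-free), when it migrates, and
#' when it incubates. The bird starts the year at its wintering site, makes
#' a two-leg northbound migration (transoceanic flight, stopover on the
#' southeast US coast, final coastal flight), breeds at the deployment
#' site, incubates daily from `nest_initiation`, then returns south via a
#' two-leg southbound migration with a stopover on the north coast of
#' South America. Default event dates follow the mid-Atlantic schedule
#' (departure in early April, nesting in early May).
#'
#' Events may be set to `NA` to script a bird that never migrates and/or
#' never nests.
#'
#' @param individual_id Label for the individual.
#' @param site Deployment (breeding) site label.
#' @param site_lat,site_lon Breeding site coordinates, degrees.
#' @param winter_lat,winter_lon Wintering site coordinates (default coastal
#'   Maranhao, Brazil).
#' @param spring_stopover,fall_stopover Length-2 `c(lat, lon)` stopover
#'   coordinates (southeast US coast; Guianas coast).
#' @param spring_departure,breeding_arrival,nest_initiation,fall_departure,winter_arrival
#'   Event days of year (1--365), strictly ordered; `NA` drops the phase.
#' @param spring_flight_h,fall_flight_h Length-2 vectors: duration (hours)
#'   of the transoceanic leg and of the final leg for each migration. All
#'   legs are sustained dry flights.
#' @param incubation_bouts List of `c(offset_h, duration_h)` daytime
#'   incubation bouts per nesting day, offsets relative to local solar noon.
#' @param incubation_days Number of consecutive days with incubation bouts.
#' @param sampling_interval_min Logger sampling interval, minutes.
#' @param seed Integer seed (wet/dry texture).
#' @return A `track_script` list, including the derived `flight_legs` tibble.
#' @export
track_script <- function(individual_id = "bird_01",
                         site = "NJ",
                         site_lat = 39.27,
                         site_lon = -75.24,
                         winter_lat = -2.6,
                         winter_lon = -44.3,
                         spring_stopover = c(32.0, -80.9),
                         fall_stopover = c(6.8, -57.9),
                         spring_departure = 94,
                         breeding_arrival = 107,
                         nest_initiation = 127,
                         fall_departure = 192,
                         winter_arrival = 215,
                         spring_flight_h = c(101, 26),
                         fall_flight_h = c(102, 26),
                         incubation_bouts = list(c(-2.5, 1.5), c(1.0, 1.5)),
                         incubation_days = 24,
                         sampling_interval_min = 5,
                         seed = 1L) {
  ev <- c(
    spring_departure = spring_departure, breeding_arrival = breeding_arrival,
    nest_initiation = nest_initiation, fall_departure = fall_departure,
    winter_arrival = winter_arrival
  )
  known <- ev[!is.na(ev)]
  .assert(all(diff(known) > 0), "event days must be strictly ordered within the year")
  .assert(all(known >= 2 & known <= 364), "event days must lie in 2..364")
  .assert(all(c(spring_flight_h, fall_flight_h) > 0), "flight durations must be > 0")

  legs <- list()
  t0 <- as.POSIXct("2013-01-01 00:00:00", tz = "UTC")
  at <- function(doy, hour) t0 + ((doy - 1) * 24 + hour) * 3600
  if (!is.na(spring_departure) && !is.na(breeding_arrival)) {
    l1_start <- at(spring_departure, 2)
    l2_end <- at(breeding_arrival, 10)
    legs <- c(legs, list(
      tibble::tibble(
        leg = "spring_1", start = l1_start,
        end = l1_start + spring_flight_h[1] * 3600,
        from_lat = winter_lat, from_lon = winter_lon,
        to_lat = spring_stopover[1], to_lon = spring_stopover[2]
      ),
      tibble::tibble(
        leg = "spring_2", start = l2_end - spring_flight_h[2] * 3600,
        end = l2_end,
        from_lat = spring_stopover[1], from_lon = spring_stopover[2],
        to_lat = site_lat, to_lon = site_lon
      )
    ))
  }
  if (!is.na(fall_departure) && !is.na(winter_arrival)) {
    l1_start <- at(fall_departure, 2)
    l2_end <- at(winter_arrival, 12)
    legs <- c(legs, list(
      tibble::tibble(
        leg = "fall_1", start = l1_start,
        end = l1_start + fall_flight_h[1] * 3600,
        from_lat = site_lat, from_lon = site_lon,
        to_lat = fall_stopover[1], to_lon = fall_stopover[2]
      ),
      tibble::tibble(
        leg = "fall_2", start = l2_end - fall_flight_h[2] * 3600,
        end = l2_end,
        from_lat = fall_stopover[1], from_lon = fall_stopover[2],
        to_lat = winter_lat, to_lon = winter_lon
      )
    ))
  }
  flight_legs <- if (length(legs)) dplyr::bind_rows(legs) else
    tibble::tibble(
      leg = character(), start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"),
      from_lat = double(), from_lon = double(),
      to_lat = double(), to_lon = double()
    )
  if (nrow(flight_legs) > 1) {
    o <- order(flight_legs$start)
    .assert(
      all(flight_legs$start[o][-1] >= flight_legs$end[o][-nrow(flight_legs)]),
      "flight legs overlap"
    )
  }

  structure(
    list(
      individual_id = individual_id, site = site,
      site_lat = site_lat, site_lon = site_lon,
      winter_lat = winter_lat, winter_lon = winter_lon,
      events = ev,
      flight_legs = flight_legs,
      incubation_bouts = incubation_bouts,
      incubation_days = as.integer(incubation_days),
      sampling_interval_min = sampling_interval_min,
      seed = as.integer(seed),
      origin = t0
    ),
    class = "track_script"
  )
}

#' Simulate a geolocator light + conductivity record from a script
#'
#' Light follows the solar day/night cycle at the scripted (possibly
#' moving) position: zero below a sun elevation of `night_angle` degrees,
#' full scale above 0 degrees, ramping linearly through twilight. During
#' scripted incubation bouts (daytime nest shading) light is forced to
#' night level. Conductivity is wet with probability 0.8 per sample in
#' daylight and 0.5 at night while the bird is stationary in salt marsh,
#' and continuously dry during flight legs. During flights the light
#' template follows the great-circle position between leg endpoints.
#'
#' @param script A [track_script()].
#' @param night_angle Sun elevation (degrees) below which light is zero.
#' @param light_max Full-scale light value.
#' @return A `geolocator_track` list: tibbles `light` (`time`, `light`),
#'   `conductivity` (`time`, `wet`), the `truth` event table (one row of
#'   scripted days of year) and the originating `script`.
#' @export
sim_geolocator_track <- function(script, night_angle = -6, light_max = 100) {
  .assert(inherits(script, "track_script"), "script must come from track_script()")
  s <- script
  step <- s$sampling_interval_min * 60
  time <- seq(s$origin, s$origin + 365 * 86400 - step, by = step)
  n <- length(time)
  el <- as.numeric(time - s$origin, units = "secs")
  doy <- floor(el / 86400) + 1
  hour <- (el %% 86400) / 3600

  lat <- rep(s$site_lat, n)
  lon <- rep(s$site_lon, n)
  in_flight <- rep(FALSE, n)
  ev <- s$events
  if (!is.na(ev["spring_departure"])) {
    pre <- time < s$flight_legs$start[s$flight_legs$leg == "spring_1"]
    lat[pre] <- s$winter_lat
    lon[pre] <- s$winter_lon
  }
  if (!is.na(ev["winter_arrival"])) {
    post <- time >= s$flight_legs$end[s$flight_legs$leg == "fall_2"]
    lat[post] <- s$winter_lat
    lon[post] <- s$winter_lon
  }
  if (nrow(s$flight_legs)) {
    legs <- s$flight_legs[order(s$flight_legs$start), ]
    for (i in seq_len(nrow(legs))) {
      lg <- legs[i, ]
      idx <- which(time >= lg$start & time < lg$end)
      if (length(idx)) {
        frac <- as.numeric(time[idx] - lg$start, units = "secs") /
          as.numeric(lg$end - lg$start, units = "secs")
        p <- .gc_interp(lg$from_lat, lg$from_lon, lg$to_lat, lg$to_lon, frac)
        lat[idx] <- p$lat
        lon[idx] <- p$lon
        in_flight[idx] <- TRUE
      }
      # stationary at the leg destination until the next leg (or year end)
      nxt <- if (i < nrow(legs)) legs$start[i + 1] else time[n] + step
      idx2 <- which(time >= lg$end & time < nxt)
      if (length(idx2)) {
        lat[idx2] <- lg$to_lat
        lon[idx2] <- lg$to_lon
      }
    }
  }

  elev <- solar_elevation(doy, hour, lat, lon)
  light <- light_max * pmin(1, pmax(0, (elev - night_angle) / (-night_angle)))

  # incubation: force light to night level during scripted daytime bouts
  nest <- ev["nest_initiation"]
  if (!is.na(nest) && length(s$incubation_bouts)) {
    noon_h <- (720 - 4 * s$site_lon - equation_of_time(doy)) / 60
    for (b in s$incubation_bouts) {
      b_start <- noon_h + b[1]
      in_bout <- doy >= nest & doy < nest + s$incubation_days &
        hour >= b_start & hour < b_start + b[2]
      light[in_bout] <- 0
    }
  }

  wet <- .with_seed(s$seed, {
    p_wet <- ifelse(elev > night_angle, 0.8, 0.5)
    as.integer(stats::runif(n) < p_wet)
  })
  wet[in_flight] <- 0L
  # a marsh bird is in the water right up to departure and on arrival, so
  # the samples bounding each flight are wet; this also pins detected
  # flight boundaries to the scripted ones
  if (any(in_flight)) {
    edges <- which(diff(in_flight) != 0)
    wet[pmax(1, edges[in_flight[edges + 1]])] <- 1L # last sample before a leg
    wet[pmin(n, edges[!in_flight[edges + 1]] + 1)] <- 1L # first after a leg
  }

  truth <- tibble::tibble(
    individual_id = s$individual_id, site = s$site,
    latitude = s$site_lat, longitude = s$site_lon,
    spring_departure = unname(ev["spring_departure"]),
    breeding_arrival = unname(ev["breeding_arrival"]),
    nest_initiation = unname(ev["nest_initiation"]),
    fall_departure = unname(ev["fall_departure"]),
    winter_arrival = unname(ev["winter_arrival"])
  )

  structure(
    list(
      light = tibble::tibble(time = time, light = light),
      conductivity = tibble::tibble(time = time, wet = wet),
      truth = truth,
      script = s
    ),
    class = "geolocator_track"
  )
}
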