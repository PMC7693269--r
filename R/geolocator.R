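#' Detect twilight times from a light series
#'
#' Finds threshold crossings of a regularly sampled light series: a rise at
#' each upward crossing and a set at each downward crossing, with the
#' crossing time linearly interpolated between samples. By convention a
#' crossing only counts as a twilight if it bounds a dark period of at
#' least `min_dark_hours` (night); this keeps short daytime shading events
#' (e.g. incubation) from masquerading as sunsets. Set
#' `min_dark_hours = 0` to keep every crossing.
#'
#' @param light A tibble with columns `time` (POSIXct) and `light`.
#' @param threshold Light level defining twilight (default 1).
#' @param min_dark_hours Minimum below-threshold spell, hours, for its
#'   bounding crossings to count as twilights.
#' @return A tibble of twilight events: `time`, `kind` (`"rise"`/`"set"`),
#'   `edited` (`"kept"`).
#' @export
detect_twilights <- function(light, threshold = 1, min_dark_hours = 4) {
  .check_cols(light, c("time", "light"), "light series")
  l <- light$light
  t <- light$time
  n <- length(l)
  if (n < 2 || all(l >= threshold) || all(l < threshold)) {
    rlang::warn("light never crosses the threshold; no twilights detected")
    return(tibble::tibble(
      time = as.POSIXct(character(), tz = "UTC"),
      kind = character(), edited = character()
    ))
  }
  dark <- l < threshold
  # runs of darkness, with durations
  r <- rle(dark)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  keep_run <- rep(TRUE, length(r$lengths))
  if (min_dark_hours > 0) {
    dur_h <- vapply(seq_along(r$lengths), function(i) {
      as.numeric(t[run_end[i]] - t[run_start[i]], units = "hours")
    }, numeric(1))
    keep_run <- !r$values | dur_h >= min_dark_hours |
      run_start == 1 | run_end == n # edge runs: duration unknown, keep
  }
  cross_time <- function(i1, i2) {
    # linear interpolation of the threshold crossing between samples i1, i2
    f <- (threshold - l[i1]) / (l[i2] - l[i1])
    t[i1] + f * as.numeric(t[i2] - t[i1], units = "secs")
  }
  events <- list()
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || !keep_run[i]) next
    s <- run_start[i]
    e <- run_end[i]
    if (s > 1) { # light -> dark: a set at the run's leading edge
      events[[length(events) + 1]] <-
        tibble::tibble(time = cross_time(s - 1, s), kind = "set")
    }
    if (e < n) { # dark -> light: a rise at the trailing edge
      events[[length(events) + 1]] <-
        tibble::tibble(time = cross_time(e, e + 1), kind = "rise")
    }
  }
  if (!length(events)) {
    return(tibble::tibble(
      time = as.POSIXct(character(), tz = "UTC"),
      kind = character(), edited = character()
    ))
  }
  out <- dplyr::arrange(dplyr::bind_rows(events), .data$time)
  out$edited <- "kept"
  out
}

# minutes-since-midnight clock time, UTC
.clock_min <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

# signed circular difference of clock minutes, in (-720, 720]
.circ_diff <- function(x, ref) {
  d <- (x - ref) %% 1440
  ifelse(d > 720, d - 1440, d)
}

#' Remove twilight outliers
#'
#' Flags twilight events whose clock time deviates by more than
#' `max_deviation_min` minutes from the median clock time of same-kind
#' events on the surrounding `neighbor_days` days, and removes them. The
#' rule is applied twice (a second pass after the first removals), so a
#' single gross outlier cannot shield a neighbour.
#'
#' @param events Twilight tibble from [detect_twilights()].
#' @param max_deviation_min Maximum tolerated deviation, minutes (35 by
#'   convention).
#' @param neighbor_days Half-width of the comparison window, days.
#' @return The events tibble with outliers removed; removed events are
#'   returned in attribute `"removed"` with `edited = "removed"`.
#' @export
filter_twilight_outliers <- function(events, max_deviation_min = 35,
                                     neighbor_days = 2) {
  if (nrow(events) == 0) return(events)
  ev <- dplyr::arrange(events, .data$time)
  removed <- ev[0, ]
  for (pass in 1:2) {
    clock <- .clock_min(ev$time)
    flag <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(ev))) {
      same <- ev$kind == ev$kind[i] &
        abs(as.numeric(ev$time - ev$time[i], units = "days")) <= neighbor_days + 0.5
      same[i] <- FALSE
      if (!any(same)) next
      ref <- clock[i] + median(.circ_diff(clock[same], clock[i]))
      flag[i] <- abs(.circ_diff(clock[i], ref)) > max_deviation_min
    }
    if (any(flag)) {
      rem <- ev[flag, ]
      rem$edited <- "removed"
      removed <- dplyr::bind_rows(removed, rem)
      ev <- ev[!flag, ]
    } else {
      break
    }
  }
  attr(ev, "removed") <- removed
  ev
}

#' Threshold positions from twilight pairs
#'
#' Converts consecutive rise/set pairs into twice-daily position
#' estimates: longitude from local apparent noon (the rise/set midpoint,
#' corrected by the equation of time; 15 degrees per hour), latitude by
#' solving the sunrise equation for the observed day length at the given
#' solar zenith angle. Latitude is undefined when the day length is within
#' `lat_tol_min` minutes of 12 h (the equinox degeneracy) or when no
#' solution exists.
#'
#' @param events Cleaned twilight tibble ([filter_twilight_outliers()]).
#' @param zenith Solar zenith angle, degrees (96 = civil twilight).
#' @param lat_tol_min Day-length tolerance around 12 h, minutes, below
#'   which latitude is left undefined.
#' @return A tibble of position estimates: `time` (pair midpoint), `doy`,
#'   `day_length_h`, `longitude`, `latitude`, `lat_defined`, `zenith`.
#' @export
threshold_positions <- function(events, zenith = 96, lat_tol_min = 10) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      time = as.POSIXct(character(), tz = "UTC"), doy = integer(),
      day_length_h = double(), longitude = double(), latitude = double(),
      lat_defined = logical(), zenith = double()
    ))
  }
  ev <- dplyr::arrange(events, .data$time)
  rises <- which(ev$kind == "rise")
  out <- purrr::map_dfr(rises, function(i) {
    j <- which(ev$kind == "set" & ev$time > ev$time[i])[1]
    if (is.na(j)) return(NULL)
    .assert(ev$time[j] > ev$time[i], "set must follow rise")
    if (as.numeric(ev$time[j] - ev$time[i], units = "hours") > 24) return(NULL)
    mid <- ev$time[i] + as.numeric(ev$time[j] - ev$time[i], units = "secs") / 2
    doy <- doy_from_time(mid)
    eqt <- equation_of_time(doy)
    noon_min <- .clock_min(mid)
    lon <- (720 - eqt - noon_min) / 4
    lon <- ((lon + 180) %% 360) - 180
    daylen_min <- as.numeric(ev$time[j] - ev$time[i], units = "mins")
    lat <- .lat_from_daylength(daylen_min, doy, zenith)
    defined <- !is.na(lat) && abs(daylen_min - 720) >= lat_tol_min
    tibble::tibble(
      time = mid, doy = doy, day_length_h = daylen_min / 60,
      longitude = lon, latitude = if (defined) lat else NA_real_,
      lat_defined = defined, zenith = zenith
    )
  })
  out
}

# solve sin(lat) sin(decl) + cos(lat) cos(decl) cos(H) = cos(zenith)
# for latitude, given the half-day hour angle H from the day length
.lat_from_daylength <- function(daylen_min, doy, zenith) {
  H <- .deg2rad(daylen_min / 8) # minutes -> degrees (4 min/deg), halved
  d <- .deg2rad(solar_declination(doy))
  a <- sin(d)
  b <- cos(d) * cos(H)
  cc <- cos(.deg2rad(zenith))
  R <- sqrt(a^2 + b^2)
  if (abs(cc) > R) return(NA_real_)
  psi <- atan2(b, a)
  cand <- c(asin(cc / R) - psi, pi - asin(cc / R) - psi)
  cand <- ((cand + pi) %% (2 * pi)) - pi
  cand <- cand[abs(cand) <= .deg2rad(89.9)]
  if (!length(cand)) return(NA_real_)
  if (length(cand) == 1) return(.rad2deg(cand))
  # two geometric roots (one per hemisphere): a day longer than the
  # equinoctial day for this zenith implies the summer hemisphere
  eq_daylen <- 8 * .rad2deg(acos(pmin(1, pmax(-1, cc / cos(d)))))
  want <- sign(d) * sign(daylen_min - eq_daylen)
  pick <- cand[sign(cand) == want]
  if (!length(pick)) pick <- cand[which.min(abs(cand))]
  .rad2deg(pick[1])
}

#' Mask latitudes around the equinoxes
#'
#' Day length carries no latitude information near the equinoxes, so
#' latitude estimates within `half_window` days of March 20 (doy 79) and
#' September 22 (doy 265) are suppressed; longitude is retained.
#'
#' @param positions Tibble from [threshold_positions()].
#' @param half_window Days either side of each equinox to mask.
#' @return The positions tibble with masked latitudes set `NA`,
#'   `lat_defined = FALSE` and a logical `equinox_masked` column.
#' @export
mask_equinox <- function(positions, half_window = 40) {
  if (nrow(positions) == 0) {
    positions$equinox_masked <- logical(0)
    return(positions)
  }
  doy <- positions$doy
  near <- function(centre) {
    d <- abs(doy - centre)
    pmin(d, 365 - d) <= half_window
  }
  masked <- near(79) | near(265)
  positions$latitude[masked] <- NA_real_
  positions$lat_defined <- positions$lat_defined & !masked
  positions$equinox_masked <- masked
  positions
}

#' Classify sustained flights from conductivity
#'
#' Migration legs over open ocean show as extended dry spells quite unlike
#' the frequent wet-dry switching of a bird living in salt marsh. Maximal
#' runs of consecutive dry samples lasting at least `min_dry_hours` are
#' returned as flights, with boundaries at the first and last dry sample.
#'
#' @param conductivity A tibble with columns `time` (POSIXct) and `wet`
#'   (0/1 or logical).
#' @param min_dry_hours Minimum dry-spell duration counted as flight.
#' @return A tibble of flight intervals: `start`, `end`, `duration_h`.
#' @export
classify_flights <- function(conductivity, min_dry_hours = 20) {
  .check_cols(conductivity, c("time", "wet"), "conductivity series")
  dry <- as.integer(conductivity$wet) == 0L
  t <- conductivity$time
  empty <- tibble::tibble(
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), duration_h = double()
  )
  if (!any(dry)) return(empty)
  r <- rle(dry)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  out <- purrr::map_dfr(which(r$values), function(i) {
    dur <- as.numeric(t[run_end[i]] - t[run_start[i]], units = "hours")
    if (dur < min_dry_hours) return(NULL)
    tibble::tibble(start = t[run_start[i]], end = t[run_end[i]], duration_h = dur)
  })
  if (nrow(out) == 0) empty else out
}

#' Detect incubation bouts and nest initiation
#'
#' A leg-mounted light sensor is shaded while its bearer incubates, so
#' daytime darkness is the signature of nesting. A bout is a run of
#' below-threshold light lasting at least `min_bout_hours` strictly
#' between a sunrise and the following sunset. Nest initiation is the
#' first day beginning a run of at least `min_days` consecutive days that
#' each contain a bout.
#'
#' @param light Light tibble (`time`, `light`).
#' @param twilights Cleaned twilight events defining daylight.
#' @param threshold Light threshold (same scale as detection).
#' @param min_bout_hours Minimum daytime dark spell counted as a bout.
#' @param min_days Consecutive bout-days required to call nest initiation.
#' @return A list: `bouts` (tibble `doy`, `start`, `end`, `duration_h`)
#'   and `nest_initiation_doy` (`NA` if no persistent run).
#' @export
detect_incubation <- function(light, twilights, threshold = 1,
                              min_bout_hours = 1, min_days = 3) {
  .check_cols(light, c("time", "light"), "light series")
  .assert(nrow(twilights) > 0 && any(twilights$kind == "rise") &&
            any(twilights$kind == "set"),
          "no daylight definition available (no usable twilights)")
  ev <- dplyr::arrange(twilights, .data$time)
  rises <- ev[ev$kind == "rise", ]
  sets <- ev[ev$kind == "set", ]
  dark <- light$light < threshold
  r <- rle(dark)
  run_end_i <- cumsum(r$lengths)
  run_start_i <- run_end_i - r$lengths + 1
  bouts <- purrr::map_dfr(which(r$values), function(i) {
    t0 <- light$time[run_start_i[i]]
    t1 <- light$time[run_end_i[i]]
    dur <- as.numeric(t1 - t0, units = "hours")
    if (dur < min_bout_hours) return(NULL)
    # strictly inside a rise -> next set interval?
    k <- findInterval(as.numeric(t0), as.numeric(rises$time))
    if (k < 1) return(NULL)
    nxt_set <- sets$time[findInterval(as.numeric(rises$time[k]), as.numeric(sets$time)) + 1]
    if (is.na(nxt_set) || t0 <= rises$time[k] || t1 >= nxt_set) return(NULL)
    tibble::tibble(
      doy = doy_from_time(t0), start = t0, end = t1, duration_h = dur
    )
  })
  nest <- NA_real_
  if (nrow(bouts) > 0) {
    days <- sort(unique(bouts$doy))
    runs <- split(days, cumsum(c(1, diff(days) != 1)))
    for (rn in runs) {
      if (length(rn) >= min_days) {
        nest <- rn[1]
        break
      }
    }
  }
  list(bouts = bouts, nest_initiation_doy = nest)
}

#' Assemble a per-individual annual-cycle event table
#'
#' Groups detected flights into migrations (flights separated by less than
#' `gap_days` of stationarity form one migration with stopovers), assigns
#' each migration a direction by comparing stationary longitudes before
#' and after the migration with the breeding-site longitude, and combines
#' flight, position and incubation evidence into the five annual-cycle
#' events and their derived durations. Missing phases yield `NA` fields.
#'
#' @param flights Flight intervals from [classify_flights()].
#' @param positions Positions from [threshold_positions()] /
#'   [mask_equinox()] (longitudes are used for direction).
#' @param incubation Result of [detect_incubation()] (or `NULL`).
#' @param site_lon Breeding-site longitude, degrees.
#' @param individual_id,site Labels carried into the table.
#' @param gap_days Maximum stationary gap within one migration.
#' @return A one-row tibble with event days of year (`spring_departure`,
#'   `breeding_arrival`, `nest_initiation`, `fall_departure`,
#'   `winter_arrival`) and durations (`spring_migration_days`,
#'   `pre_nesting_days`, `nesting_period_days`, `fall_migration_days`,
#'   `wintering_days`).
#' @export
build_event_table <- function(flights, positions, incubation = NULL,
                              site_lon, individual_id = "bird",
                              site = "site", gap_days = 30) {
  ev <- list(
    spring_departure = NA_real_, breeding_arrival = NA_real_,
    nest_initiation = NA_real_, fall_departure = NA_real_,
    winter_arrival = NA_real_
  )
  if (!is.null(incubation)) ev$nest_initiation <- incubation$nest_initiation_doy

  if (nrow(flights) > 0) {
    fl <- dplyr::arrange(flights, .data$start)
    gap <- c(Inf, as.numeric(fl$start[-1] - fl$end[-nrow(fl)], units = "days"))
    fl$cluster <- cumsum(gap >= gap_days)
    clusters <- fl |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end), .groups = "drop"
      )
    lon_near <- function(t0, t1) {
      sel <- positions$time >= t0 & positions$time <= t1
      if (!any(sel)) return(NA_real_)
      median(positions$longitude[sel], na.rm = TRUE)
    }
    clusters$dir <- vapply(seq_len(nrow(clusters)), function(i) {
      before <- lon_near(clusters$start[i] - 6 * 86400, clusters$start[i] - 0.25 * 86400)
      after <- lon_near(clusters$end[i] + 0.25 * 86400, clusters$end[i] + 6 * 86400)
      if (is.na(before) || is.na(after)) return(NA_character_)
      if (abs(after - site_lon) < abs(before - site_lon)) "northbound" else "southbound"
    }, character(1))
    nb <- clusters[!is.na(clusters$dir) & clusters$dir == "northbound", ]
    sb <- clusters[!is.na(clusters$dir) & clusters$dir == "southbound", ]
    if (nrow(nb) > 0) {
      ev$spring_departure <- doy_from_time(nb$start[1])
      ev$breeding_arrival <- doy_from_time(nb$end[nrow(nb)])
    }
    if (nrow(sb) > 0) {
      ev$fall_departure <- doy_from_time(sb$start[1])
      ev$winter_arrival <- doy_from_time(sb$end[nrow(sb)])
    }
  }

  d <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else b - a
  tibble::tibble(
    individual_id = individual_id, site = site,
    spring_departure = ev$spring_departure,
    breeding_arrival = ev$breeding_arrival,
    nest_initiation = ev$nest_initiation,
    fall_departure = ev$fall_departure,
    winter_arrival = ev$winter_arrival,
    spring_migration_days = d(ev$spring_departure, ev$breeding_arrival),
    pre_nesting_days = d(ev$breeding_arrival, ev$nest_initiation),
    nesting_period_days = d(ev$nest_initiation, ev$fall_departure),
    fall_migration_days = d(ev$fall_departure, ev$winter_arrival),
    wintering_days = if (is.na(ev$winter_arrival) || is.na(ev$spring_departure)) {
      NA_real_
    } else {
      ev$spring_departure + 365 - ev$winter_arrival
    }
  )
}

#' Run the full event-detection chain on one track
#'
#' Convenience wrapper: twilights, outlier cleaning, positions, equinox
#' mask, flights, incubation, event table.
#'
#' @param track A `geolocator_track` (from [sim_geolocator_track()]) or a
#'   list with `light` and `conductivity` tibbles.
#' @param site_lon Breeding-site longitude; defaults to the scripted value
#'   when present.
#' @param threshold,zenith,min_dry_hours,gap_days Detection settings.
#' @param individual_id,site Labels; default to scripted values.
#' @return The one-row event tibble from [build_event_table()].
#' @export
detect_annual_cycle <- function(track, site_lon = NULL, threshold = 1,
                                zenith = 96, min_dry_hours = 20,
                                gap_days = 30, individual_id = NULL,
                                site = NULL) {
  sc <- track$script
  site_lon <- site_lon %||% sc$site_lon
  individual_id <- individual_id %||% (sc$individual_id %||% "bird")
  site <- site %||% (sc$site %||% "site")
  tw <- detect_twilights(track$light, threshold = threshold)
  tw <- filter_twilight_outliers(tw)
  pos <- mask_equinox(threshold_positions(tw, zenith = zenith))
  fl <- classify_flights(track$conductivity, min_dry_hours = min_dry_hours)
  inc <- detect_incubation(track$light, tw, threshold = threshold)
  build_event_table(fl, pos, inc,
    site_lon = site_lon,
    individual_id = individual_id, site = site, gap_days = gap_days
  )
}
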