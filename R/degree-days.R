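#' Daily growing degree days by the single sine method
#'
#' Fits one sine period to the day's temperature course, with mean
#' `(tmin + tmax)/2` and amplitude `(tmax - tmin)/2`, and integrates the
#' excess over `base` across the portion of the day where the curve is
#' above `base` (the classical Baskerville--Emin interception cases).
#'
#' @param tmin,tmax Daily minimum and maximum temperature, deg C
#'   (vectorized; `tmax >= tmin`).
#' @param base Base (threshold) temperature, deg C; 10 is the conventional
#'   threshold for *Spartina* growth.
#' @return Degree-days (deg C day), one value per input day.
#' @export
daily_gdd <- function(tmin, tmax, base = 10) {
  .assert(all(is.finite(tmin)) && all(is.finite(tmax)) && all(is.finite(base)),
          "temperatures must be finite")
  .assert(all(tmax >= tmin), "tmax must be >= tmin")
  m <- (tmin + tmax) / 2
  w <- (tmax - tmin) / 2
  out <- numeric(length(m))
  above <- tmin >= base
  below <- tmax <= base
  out[above] <- (m - base)[above]
  out[below] <- 0
  mid <- !above & !below
  if (any(mid)) {
    theta <- asin(pmin(1, pmax(-1, (base - m[mid]) / w[mid])))
    out[mid] <- ((m[mid] - base) * (pi / 2 - theta) + w[mid] * cos(theta)) / pi
  }
  out
}

#' Per-year cumulative growing degree days
#'
#' Accumulates [daily_gdd()] within each calendar year of a daily station
#' record. Records must be contiguous within year; gaps of up to
#' `max_gap` days are filled by linear interpolation of `tmin`/`tmax`
#' (with a message), longer gaps are an error.
#'
#' @param daily A tibble with columns `year`, `doy`, `tmin`, `tmax`
#'   (as produced by [sim_climate()]); extra columns are carried along.
#' @param base Base temperature, deg C.
#' @param start_doy First day of accumulation (default 1).
#' @param max_gap Longest gap (days) filled by interpolation.
#' @return A tibble with `year`, `doy`, `gdd`, `cum_gdd` (plus `station_id`
#'   and `latitude` if present in the input).
#' @export
cumulative_gdd <- function(daily, base = 10, start_doy = 1, max_gap = 3) {
  .check_cols(daily, c("year", "doy", "tmin", "tmax"), "daily record")
  carry <- intersect(c("station_id", "latitude"), names(daily))
  daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(carry, "year")))) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$doy)
      full <- tibble::tibble(doy = seq(min(df$doy), max(df$doy)))
      merged <- dplyr::left_join(full, df[, c("doy", "tmin", "tmax")], by = "doy")
      gap <- is.na(merged$tmin) | is.na(merged$tmax)
      if (any(gap)) {
        runs <- rle(gap)
        .assert(max(runs$lengths[runs$values]) <= max_gap,
                sprintf("temperature record has a gap longer than %d days", max_gap))
        merged$tmin <- stats::approx(merged$doy[!gap], merged$tmin[!gap],
                                     xout = merged$doy)$y
        merged$tmax <- stats::approx(merged$doy[!gap], merged$tmax[!gap],
                                     xout = merged$doy)$y
        message(sum(gap), " missing day(s) filled by linear interpolation")
      }
      merged <- merged[merged$doy >= start_doy, ]
      merged$gdd <- daily_gdd(merged$tmin, merged$tmax, base)
      merged$cum_gdd <- cumsum(merged$gdd)
      merged[, c("doy", "gdd", "cum_gdd")]
    }) |>
    dplyr::ungroup()
}

#' Multi-year average degree-day climatology
#'
#' Pointwise mean of per-year cumulative degree-day series across a set of
#' years, per day of year: the substrate for the spring-onset statistic.
#'
#' @param cum A tibble from [cumulative_gdd()].
#' @param years Years to average over (default: all present).
#' @return A tibble with one row per `doy` and column `cum_gdd`
#'   (per station if `station_id` is present), plus `n_years`.
#' @export
average_climatology <- function(cum, years = NULL) {
  .check_cols(cum, c("year", "doy", "cum_gdd"), "cumulative series")
  if (!is.null(years)) cum <- dplyr::filter(cum, .data$year %in% years)
  .assert(nrow(cum) > 0, "no complete year in the requested subset")
  carry <- intersect(c("station_id", "latitude"), names(cum))
  cum |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(carry, "doy")))) |>
    dplyr::summarise(
      cum_gdd = mean(.data$cum_gdd),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Degree-day jerk (third derivative of cumulative GDD)
#'
#' Smooths a cumulative degree-day climatology with an iterated centred
#' moving average and differentiates three times by central finite
#' differences at 1-day spacing. The spring maximum of this series
#' ("temperature acceleration") is a standard onset-of-spring proxy.
#'
#' A third difference amplifies high-frequency noise severely, and a
#' single-pass (box) moving average leaves sharp kernel edges that
#' dominate it; iterating the average (`passes` > 1) yields a smooth
#' quasi-Gaussian kernel whose third difference responds to the seasonal
#' signal rather than to day-to-day noise. Days within
#' `3 + passes * halfwidth` of either end are undefined (`NA`).
#'
#' @param clim A tibble with columns `doy` and `cum_gdd` (one station), as
#'   from [average_climatology()].
#' @param halfwidth Half-width of the centred moving average, days
#'   (window `2 * halfwidth + 1`); 0 disables smoothing.
#' @param passes Number of moving-average passes (default 3).
#' @return The input with columns `smoothed` and `jerk`
#'   (degree-days / day^3) added.
#' @export
gdd_jerk <- function(clim, halfwidth = 15, passes = 3) {
  .check_cols(clim, c("doy", "cum_gdd"), "climatology")
  .assert(halfwidth >= 0, "halfwidth must be >= 0")
  .assert(passes >= 1, "passes must be >= 1")
  clim <- dplyr::arrange(clim, .data$doy)
  n <- nrow(clim)
  .assert(n >= 7 + 2 * passes * halfwidth, "climatology too short for the jerk stencil")
  sm <- clim$cum_gdd
  if (halfwidth > 0) {
    k <- 2 * halfwidth + 1
    for (p in seq_len(passes)) {
      sm <- as.numeric(stats::filter(sm, rep(1 / k, k), sides = 2))
    }
  }
  jerk <- rep(NA_real_, n)
  edge <- 3 + if (halfwidth > 0) passes * halfwidth else 0
  i <- seq(edge + 1, n - edge)
  # central third difference, h = 1 day: (f(+2) - 2 f(+1) + 2 f(-1) - f(-2)) / 2
  jerk[i] <- (sm[i + 2] - 2 * sm[i + 1] + 2 * sm[i - 1] - sm[i - 2]) / 2
  clim$smoothed <- sm
  clim$jerk <- jerk
  class(clim) <- c("marshwave_jerk", class(clim))
  clim
}

#' Spring onset from the degree-day jerk
#'
#' The day of year at which the jerk series peaks inside the spring search
#' window; ties are broken toward the earliest day.
#'
#' @param jerk_tbl Output of [gdd_jerk()].
#' @param window Length-2 day-of-year search window (default Jan 1 --
#'   Jun 30, excluding autumn deceleration features).
#' @return A one-row tibble: `onset_doy`, `jerk_value`.
#' @export
spring_onset <- function(jerk_tbl, window = c(1, 181)) {
  .check_cols(jerk_tbl, c("doy", "jerk"), "jerk series")
  sub <- jerk_tbl[jerk_tbl$doy >= window[1] & jerk_tbl$doy <= window[2] &
                    !is.na(jerk_tbl$jerk), ]
  .assert(nrow(sub) > 0, "jerk is undefined everywhere in the onset window")
  i <- which.max(sub$jerk) # which.max takes the first maximum: earliest-day tie rule
  tibble::tibble(onset_doy = sub$doy[i], jerk_value = sub$jerk[i])
}

#' Has spring onset shifted between two periods?
#'
#' Computes the spring-onset day for each station under two climatologies
#' (e.g. a 30-year and a more recent 10-year average) and applies a
#' classical matched-pairs t-test to the per-station differences
#' (`b - a`, negative = earlier in period b).
#'
#' @param clim_a,clim_b Climatology tibbles with `station_id`, `doy`,
#'   `cum_gdd`, covering the same stations.
#' @param halfwidth,passes,window Passed to [gdd_jerk()] and
#'   [spring_onset()].
#' @return A one-row tibble: `mean_shift_days`, `t`, `df`, `p_value`,
#'   `n_stations`, plus the per-station differences as attribute
#'   `"per_station"`.
#' @export
onset_shift <- function(clim_a, clim_b, halfwidth = 15, passes = 3,
                        window = c(1, 181)) {
  .check_cols(clim_a, c("station_id", "doy", "cum_gdd"), "climatology a")
  .check_cols(clim_b, c("station_id", "doy", "cum_gdd"), "climatology b")
  stations <- intersect(unique(clim_a$station_id), unique(clim_b$station_id))
  .assert(length(stations) >= 2, "need at least 2 common stations")
  onset_of <- function(clim, st) {
    spring_onset(
      gdd_jerk(clim[clim$station_id == st, ], halfwidth, passes),
      window
    )$onset_doy
  }
  per <- purrr::map_dfr(stations, function(st) {
    tibble::tibble(
      station_id = st,
      onset_a = onset_of(clim_a, st),
      onset_b = onset_of(clim_b, st)
    )
  })
  d <- per$onset_b - per$onset_a
  if (sd(d) == 0) {
    tt <- list(
      statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      parameter = length(d) - 1,
      p.value = if (mean(d) == 0) 1 else 0
    )
  } else {
    tt <- t.test(d)
  }
  out <- tibble::tibble(
    mean_shift_days = mean(d),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_stations = length(d)
  )
  attr(out, "per_station") <- per
  out
}
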