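# square-wave light helper: day from 06:00 to 18:00 UTC
square_light <- function(days = 3, step_min = 10, level = 64) {
  t0 <- as.POSIXct("2013-06-01 00:00:00", tz = "UTC")
  time <- seq(t0, by = step_min * 60, length.out = days * 24 * 60 / step_min)
  h <- (as.numeric(time - t0, units = "hours")) %% 24
  tibble::tibble(time = time, light = ifelse(h >= 6 & h < 18, level, 0))
}

test_that("twilight detection finds one interpolated rise/set pair per day", {
  tw <- detect_twilights(square_light(days = 4), threshold = 1)
  expect_equal(sum(tw$kind == "rise"), 4)
  expect_equal(sum(tw$kind == "set"), 4)
  # with the dark-period gate disabled the result is the same here (all
  # dark spells are full nights)
  tw_all <- detect_twilights(square_light(days = 4), threshold = 1,
                             min_dark_hours = 0)
  expect_equal(nrow(tw_all), nrow(tw))
  rises <- tw$time[tw$kind == "rise"]
  hours <- as.numeric(format(rises, "%H")) + as.numeric(format(rises, "%M")) / 60
  expect_true(all(abs(hours - 6) <= 10 / 60 + 0.01))
  # alternating rise/set after sorting
  expect_true(all(rle(tw$kind)$lengths == 1))
})

test_that("twilight detection handles degenerate light series", {
  flat <- square_light(2)
  flat$light <- 50
  expect_warning(tw <- detect_twilights(flat, threshold = 100), "threshold")
  expect_equal(nrow(tw), 0)
})

test_that("amplitude scaling does not change detected twilight days", {
  sc <- track_script(seed = 21)
  tr <- sim_geolocator_track(sc)
  tw1 <- detect_twilights(tr$light)
  scaled <- tr$light
  scaled$light <- scaled$light * 10
  tw2 <- detect_twilights(scaled)
  expect_equal(nrow(tw1), nrow(tw2))
  expect_true(all(abs(as.numeric(tw1$time - tw2$time, units = "mins")) <= 5))
})

test_that("the outlier filter removes gross deviations and spares seasonal drift", {
  day <- as.POSIXct("2013-05-01 00:00:00", tz = "UTC") + (0:19) * 86400
  const <- tibble::tibble(
    time = c(day + 6 * 3600, day + 18 * 3600),
    kind = rep(c("rise", "set"), each = 20),
    edited = "kept"
  )
  expect_equal(nrow(filter_twilight_outliers(const)), 40)
  # one sunrise displaced by 60 minutes is removed, and only that one
  shifted <- const
  shifted$time[10] <- shifted$time[10] + 3600
  out <- filter_twilight_outliers(shifted)
  expect_equal(nrow(out), 39)
  removed <- attr(out, "removed")
  expect_equal(removed$time, shifted$time[10])
  # a 2 min/day drift is not an outlier
  drift <- const
  drift$time <- drift$time + rep(0:19, 2) * 120
  expect_equal(nrow(filter_twilight_outliers(drift)), 40)
})

test_that("longitude follows local solar noon at 15 degrees per hour", {
  # symmetric twilights around a chosen UTC noon; compensate the equation
  # of time so apparent noon sits exactly at the chosen clock time
  mk_pair <- function(date, noon_h, halfday_h) {
    doy <- marshwave::doy_from_time(as.POSIXct(date, tz = "UTC"))
    eqt_min <- marshwave::equation_of_time(doy)
    noon <- as.POSIXct(date, tz = "UTC") + noon_h * 3600 - eqt_min * 60
    tibble::tibble(
      time = c(noon - halfday_h * 3600, noon + halfday_h * 3600),
      kind = c("rise", "set"), edited = "kept"
    )
  }
  p1 <- threshold_positions(mk_pair("2013-06-10", 12, 7))
  expect_equal(p1$longitude, 0, tolerance = 0.01)
  p2 <- threshold_positions(mk_pair("2013-06-10", 17, 7))
  expect_equal(p2$longitude, -75, tolerance = 0.01)
  # set before rise in the pair ordering is rejected upstream by pairing:
  # a series with only a set yields no positions
  lone <- tibble::tibble(
    time = as.POSIXct("2013-06-10 22:00:00", tz = "UTC"),
    kind = "set", edited = "kept"
  )
  expect_equal(nrow(threshold_positions(lone)), 0)
})

test_that("threshold positions round-trip the synthetic track away from the equinoxes", {
  sc <- track_script(
    spring_departure = NA, breeding_arrival = NA, nest_initiation = NA,
    fall_departure = NA, winter_arrival = NA, seed = 22
  )
  tr <- sim_geolocator_track(sc)
  pos <- threshold_positions(filter_twilight_outliers(detect_twilights(tr$light)))
  sub <- pos[pos$doy >= 139 & pos$doy <= 179 & pos$lat_defined, ] # 60-100 d past Mar 20
  expect_gt(nrow(sub), 30)
  expect_lt(max(abs(sub$longitude - sc$site_lon)), 0.5)
  expect_lt(max(abs(sub$latitude - sc$site_lat)), 2)
})

test_that("equinox masking suppresses latitude but keeps longitude", {
  pos <- tibble::tibble(
    time = as.POSIXct(c("2013-03-20 12:00", "2013-06-21 12:00"), tz = "UTC"),
    doy = c(79L, 172L), day_length_h = c(12.1, 15),
    longitude = c(-75, -75), latitude = c(39, 39),
    lat_defined = c(TRUE, TRUE), zenith = 96
  )
  m <- mask_equinox(pos)
  expect_true(is.na(m$latitude[1]))
  expect_equal(m$longitude[1], -75)
  expect_equal(m$latitude[2], 39)
  # count masked days over a daily year-long sequence: 2 windows of 81 days
  yr <- tibble::tibble(
    time = as.POSIXct("2013-01-01", tz = "UTC") + (0:364) * 86400,
    doy = 1:365, day_length_h = 12, longitude = 0, latitude = 10,
    lat_defined = TRUE, zenith = 96
  )
  expect_equal(sum(mask_equinox(yr)$equinox_masked), 2 * (2 * 40 + 1))
})

test_that("flight classification finds exactly the long dry runs", {
  t0 <- as.POSIXct("2013-01-01", tz = "UTC")
  time <- seq(t0, by = 600, length.out = 12 * 144)
  wet <- rep(1L, length(time))
  expect_equal(nrow(classify_flights(tibble::tibble(time = time, wet = wet))), 0)
  # one 96 h dry run
  wet2 <- wet
  wet2[289:(288 + 96 * 6)] <- 0L
  fl <- classify_flights(tibble::tibble(time = time, wet = wet2))
  expect_equal(nrow(fl), 1)
  expect_lte(abs(fl$duration_h - 96), 1 / 6 + 1e-9)
  # short dry spells below the threshold are ignored
  wet3 <- wet
  wet3[10:40] <- 0L
  expect_equal(nrow(classify_flights(tibble::tibble(time = time, wet = wet3))), 0)
})

test_that("incubation is read from daytime darkness only", {
  sc <- track_script(seed = 23)
  tr <- sim_geolocator_track(sc)
  tw <- filter_twilight_outliers(detect_twilights(tr$light))
  inc <- detect_incubation(tr$light, tw)
  expect_equal(inc$nest_initiation_doy, sc$events[["nest_initiation"]])
  expect_true(all(inc$bouts$duration_h >= 1))
  # darkness only at night (the same track outside the nesting period)
  pre <- tr$light[marshwave::doy_from_time(tr$light$time) < 60, ]
  tw_pre <- filter_twilight_outliers(detect_twilights(pre))
  inc_pre <- detect_incubation(pre, tw_pre)
  expect_equal(nrow(inc_pre$bouts), 0)
  expect_error(detect_incubation(tr$light, tw[0, ]), "daylight")
})

test_that("the event table reproduces a scripted mid-Atlantic schedule within a day", {
  sc <- track_script(
    spring_departure = 94, breeding_arrival = 107, nest_initiation = 127,
    fall_departure = 192, winter_arrival = 215, seed = 24
  )
  tr <- sim_geolocator_track(sc)
  ev <- detect_annual_cycle(tr)
  for (e in c("spring_departure", "breeding_arrival", "nest_initiation",
              "fall_departure", "winter_arrival")) {
    expect_lte(abs(ev[[e]] - sc$events[[e]]), 1)
  }
  # durations are exact differences of their bounding events
  expect_equal(ev$spring_migration_days, ev$breeding_arrival - ev$spring_departure)
  expect_equal(ev$pre_nesting_days, ev$nest_initiation - ev$breeding_arrival)
  expect_equal(ev$nesting_period_days, ev$fall_departure - ev$nest_initiation)
  expect_equal(ev$fall_migration_days, ev$winter_arrival - ev$fall_departure)
  expect_equal(ev$wintering_days, ev$spring_departure + 365 - ev$winter_arrival)
})

test_that("a single nonstop southbound flight yields that flight's duration as fall migration", {
  t0 <- as.POSIXct("2013-01-01", tz = "UTC")
  flights <- tibble::tibble(
    start = t0 + 191 * 86400,
    end = t0 + 195 * 86400,
    duration_h = 96
  )
  pos <- tibble::tibble(
    time = c(t0 + 186 * 86400, t0 + 199 * 86400),
    doy = c(187L, 200L), day_length_h = c(14, 13),
    longitude = c(-75, -44), latitude = c(39, -2),
    lat_defined = TRUE, zenith = 96
  )
  ev <- build_event_table(flights, pos, incubation = NULL, site_lon = -75)
  expect_equal(ev$fall_migration_days, 4)
  expect_true(is.na(ev$spring_departure))
  expect_true(is.na(ev$nest_initiation))
})
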