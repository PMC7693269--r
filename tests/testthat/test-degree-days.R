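test_that("single-sine degree days reproduce the standard interception cases", {
  expect_equal(daily_gdd(12, 18, 10), 5) # whole day above base: mean - base
  expect_equal(daily_gdd(2, 8, 10), 0) # whole day below base
  # mean equal to base: closed form amplitude / pi
  expect_equal(daily_gdd(5, 15, 10), 5 / pi, tolerance = 1e-9)
  expect_error(daily_gdd(15, 5, 10), "tmax")
})

test_that("single-sine degree days agree with numerical quadrature", {
  set.seed(101)
  for (i in 1:200) {
    tmin <- runif(1, -15, 25)
    tmax <- tmin + runif(1, 0, 20)
    base <- runif(1, -5, 25)
    expect_lt(abs(daily_gdd(tmin, tmax, base) - quadrature_gdd(tmin, tmax, base)),
              1e-6)
  }
})

test_that("raising the base temperature never increases daily degree days", {
  set.seed(102)
  tmin <- runif(300, -15, 25)
  tmax <- tmin + runif(300, 0, 20)
  g1 <- daily_gdd(tmin, tmax, base = 8)
  g2 <- daily_gdd(tmin, tmax, base = 12)
  expect_true(all(g2 <= g1 + 1e-12))
})

test_that("cumulative degree days conserve daily sums and handle gaps", {
  d <- tibble::tibble(
    year = 1, doy = 1:365,
    tmin = 8 + 10 * cos(2 * pi * (1:365 - 200) / 365) - 4,
    tmax = 8 + 10 * cos(2 * pi * (1:365 - 200) / 365) + 4
  )
  cum <- cumulative_gdd(d)
  expect_equal(max(cum$cum_gdd), sum(cum$gdd))
  expect_true(all(diff(cum$cum_gdd) >= 0))
  # constant daily gdd accumulates linearly
  dc <- tibble::tibble(year = 1, doy = 1:60, tmin = 14, tmax = 18)
  cc <- cumulative_gdd(dc)
  expect_equal(cc$cum_gdd, 6 * (1:60))
  # all below base: identically zero
  db <- tibble::tibble(year = 1, doy = 1:60, tmin = 0, tmax = 5)
  expect_equal(cumulative_gdd(db)$cum_gdd, rep(0, 60))
  # a 2-day gap is interpolated, a 5-day gap errors
  dg <- dc[-(30:31), ]
  expect_message(cg <- cumulative_gdd(dg), "interpolation")
  expect_equal(nrow(cg), 60)
  expect_error(suppressMessages(cumulative_gdd(dc[-(30:34), ])), "gap")
})

test_that("climatology averaging is the pointwise mean over years", {
  d1 <- tibble::tibble(year = 1, doy = 1:100, cum_gdd = 2 * (1:100))
  d2 <- tibble::tibble(year = 2, doy = 1:100, cum_gdd = 4 * (1:100))
  avg <- average_climatology(dplyr::bind_rows(d1, d2))
  expect_equal(avg$cum_gdd, 3 * (1:100)) # slope (2 + 4) / 2
  one <- average_climatology(d1)
  expect_equal(one$cum_gdd, d1$cum_gdd)
  expect_error(average_climatology(d1, years = 1999), "subset")
})

test_that("the jerk operator is exact for cubics and silent on linear series", {
  lin <- tibble::tibble(doy = 1:120, cum_gdd = 3.7 * (1:120))
  jl <- gdd_jerk(lin, halfwidth = 5, passes = 2)
  expect_lt(max(abs(jl$jerk), na.rm = TRUE), 1e-9)
  cub <- tibble::tibble(doy = 1:120, cum_gdd = 0.002 * (1:120)^3)
  jc <- gdd_jerk(cub, halfwidth = 0)
  expect_equal(unique(round(jc$jerk[!is.na(jc$jerk)], 10)), 0.012)
})

test_that("the finite-difference jerk of a logistic matches its analytic third derivative", {
  k <- 0.08
  m <- 180
  L <- 2000
  clim <- tibble::tibble(doy = 1:365, cum_gdd = L / (1 + exp(-k * (1:365 - m))))
  j <- gdd_jerk(clim, halfwidth = 0)
  an <- logistic_jerk_analytic(1:365, L, k, m)
  ok <- !is.na(j$jerk)
  expect_lt(max(abs(j$jerk[ok] - an[ok])) / max(abs(an)), 0.01)
  # the onset (argmax of the jerk) matches a dense evaluation of the analytic form
  dense <- seq(4, 362, by = 0.01)
  an_peak <- dense[which.max(logistic_jerk_analytic(dense, L, k, m))]
  on <- spring_onset(j, window = c(1, 181))
  expect_lte(abs(on$onset_doy - an_peak), 1)
})

test_that("spring onset breaks ties toward the earliest day and validates its window", {
  flat <- tibble::tibble(doy = 1:100, jerk = c(rep(NA, 10), rep(2, 80), rep(NA, 10)))
  expect_equal(spring_onset(flat, window = c(20, 60))$onset_doy, 20)
  allna <- tibble::tibble(doy = 1:100, jerk = NA_real_)
  expect_error(spring_onset(allna), "undefined")
})

test_that("translating the temperature series translates the onset exactly", {
  p <- climate_params(noise_sd = 0, years = 1)
  d <- sim_climate(p, 40)
  base_onset <- spring_onset(gdd_jerk(average_climatology(cumulative_gdd(d))))
  for (k in c(4, -6)) {
    dk <- d
    dk$tmin <- d$tmin[((seq_len(365) - 1 - k) %% 365) + 1]
    dk$tmax <- d$tmax[((seq_len(365) - 1 - k) %% 365) + 1]
    ok <- spring_onset(gdd_jerk(average_climatology(cumulative_gdd(dk))))
    expect_equal(ok$onset_doy - base_onset$onset_doy, k)
  }
})

test_that("onset_shift recovers scripted shifts between climatology periods", {
  p <- climate_params(noise_sd = 0, years = 1)
  mk_clim <- function(peak_shift, st) {
    pp <- climate_params(noise_sd = 0, years = 1, peak_day = p$peak_day + peak_shift)
    cl <- average_climatology(cumulative_gdd(sim_climate(pp, 40, station_id = st)))
    cl$station_id <- st
    cl
  }
  stations <- paste0("st", 1:3)
  clim_a <- purrr::map_dfr(stations, function(st) mk_clim(0, st))
  # identical periods: zero shift, t = 0, p = 1
  same <- onset_shift(clim_a, clim_a)
  expect_equal(same$mean_shift_days, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # every station 4 days earlier: mean shift exactly -4
  clim_b <- purrr::map_dfr(stations, function(st) mk_clim(-4, st))
  shifted <- onset_shift(clim_a, clim_b)
  expect_equal(shifted$mean_shift_days, -4)
})

test_that("a simulated multi-station advance is recovered within 2 SE", {
  set.seed(104)
  stations <- paste0("st", 1:7)
  # integer station-level shifts (the onset statistic lives on whole days)
  shifts <- round(-3.6 + rnorm(7, 0, 1))
  mk <- function(st, sh) {
    pp <- climate_params(noise_sd = 0, years = 1, peak_day = 200 + sh)
    cl <- average_climatology(cumulative_gdd(sim_climate(pp, 40, station_id = st)))
    cl$station_id <- st
    cl
  }
  clim_a <- purrr::map_dfr(stations, function(st) mk(st, 0))
  clim_b <- purrr::map_dfr(seq_along(stations), function(i) mk(stations[i], shifts[i]))
  res <- onset_shift(clim_a, clim_b)
  se <- sd(shifts) / sqrt(7)
  expect_lt(abs(res$mean_shift_days - mean(shifts)), max(2 * se, 1e-9) + 1e-9)
  expect_lt(res$p_value, 0.05)
})
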