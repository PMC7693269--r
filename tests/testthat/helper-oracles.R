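# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of closed forms, loops
# instead of vectorized cumsums, root-finding instead of the sunrise
# equation.

# numerical quadrature of max(0, T(t) - base) over one sine period:
# composite Simpson on a fine grid (adaptive rules misjudge the kink
# where the sine crosses the base)
quadrature_gdd <- function(tmin, tmax, base, n = 40000L) {
  t <- seq(0, 1, length.out = n + 1)
  y <- pmax(0, (tmin + tmax) / 2 + (tmax - tmin) / 2 * sin(2 * pi * t) - base)
  h <- 1 / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
}

# analytic third derivative of L / (1 + exp(-k (d - m)))
logistic_jerk_analytic <- function(d, L, k, m) {
  s <- 1 / (1 + exp(-k * (d - m)))
  L * k^3 * s * (1 - s) * (1 - 6 * s + 6 * s^2)
}

# brute-force maximally selected statistic: explicit loop over admissible
# cutpoints, statistic computed from group sums and population variance
brute_force_maxstat <- function(x, y, min_prop = 0.1) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  ux <- unique(xs)
  cuts <- (ux[-length(ux)] + ux[-1]) / 2
  best_t <- -Inf
  best_cut <- NA_real_
  for (cc in cuts) {
    n1 <- sum(xs <= cc)
    if (n1 < ceiling(min_prop * n) || (n - n1) < ceiling(min_prop * n)) next
    S <- sum(ys[xs <= cc])
    mu <- mean(ys)
    sig2 <- sum((ys - mu)^2) / n
    tt <- if (sig2 == 0) 0 else abs(S - n1 * mu) / sqrt(n1 * (n - n1) / (n - 1) * sig2)
    if (tt > best_t + 1e-12) {
      best_t <- tt
      best_cut <- cc
    }
  }
  list(t_max = best_t, cutpoint = best_cut)
}

# continuous-time solution of the light-threshold crossing: root of
# solar elevation minus the target elevation, bracketed around an hour
solar_crossing_utc <- function(doy, latitude, longitude, elev_target,
                               rising = TRUE) {
  f <- function(h) {
    marshwave::solar_elevation(doy, h, latitude, longitude) - elev_target
  }
  hs <- seq(0, 24, by = 0.25)
  vals <- vapply(hs, f, numeric(1))
  idx <- which(diff(sign(vals)) != 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(hs[i], hs[i + 1]), tol = 1e-7)$root
  }, numeric(1))
  slopes <- vapply(roots, function(r) f(r + 1e-3) - f(r), numeric(1))
  roots[if (rising) slopes > 0 else slopes < 0][1]
}

# simulate one green-wave dataset from known coefficients with AR(1)
# within-study errors scaled by known per-observation SDs
simulate_greenwave <- function(beta, rho, lats = seq(31, 45, length.out = 8),
                               n_per = 25, se_range = c(0.03, 0.08)) {
  purrr::map_dfr(seq_along(lats), function(i) {
    doy <- seq(60, 240, length.out = n_per)
    se <- stats::runif(n_per, se_range[1], se_range[2])
    e <- numeric(n_per)
    e[1] <- stats::rnorm(1)
    for (j in seq(2, n_per)) {
      e[j] <- rho * e[j - 1] + stats::rnorm(1, 0, sqrt(1 - rho^2))
    }
    y <- beta[1] + beta[2] * doy + beta[3] * lats[i] + beta[4] * doy * lats[i] +
      e * se
    tibble::tibble(
      study_id = sprintf("s%d", i), latitude = lats[i], doy = doy,
      stage = y, stage_se = se, weight = 1 / se^2
    )
  })
}

# randomized track script anchored to the coupled synthetic world
random_track_script <- function(i, biomass = marshwave::biomass_params()) {
  sites <- data.frame(
    site = c("NJ", "MA_south", "MA_north_ME"),
    lat = c(39.27, 41.33, 43.03),
    lon = c(-75.24, -70.01, -70.65)
  )
  s <- sites[(i %% 3) + 1, ]
  nest <- round(marshwave::true_stage_date(biomass, 0.295, s$lat)) +
    sample(-5:5, 1)
  marshwave::track_script(
    individual_id = sprintf("sim_%03d", i), site = s$site,
    site_lat = s$lat + stats::runif(1, -0.3, 0.3),
    site_lon = s$lon + stats::runif(1, -0.5, 0.5),
    spring_departure = nest - 33 + sample(-2:2, 1),
    breeding_arrival = nest - 20 + sample(-2:2, 1),
    nest_initiation = nest,
    fall_departure = nest + 65 + sample(-3:3, 1),
    winter_arrival = nest + 88 + sample(-3:3, 1),
    seed = 5000L + i
  )
}
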