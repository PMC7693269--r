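mk_timing <- function(site_eff = c(A = 127, B = 139, C = 146), ind_sd = 2,
                      res_sd = 3, n_ind = 5:8, p_twice = 0.3) {
  purrr::map_dfr(names(site_eff), function(s) {
    n <- sample(n_ind, 1)
    purrr::map_dfr(seq_len(n), function(i) {
      b <- rnorm(1, 0, ind_sd)
      yrs <- if (runif(1) < p_twice) 2 else 1
      tibble::tibble(
        individual_id = paste0(s, i), site = s,
        doy = site_eff[s] + b + rnorm(yrs, 0, res_sd)
      )
    })
  })
}

test_that("the random-intercept fit matches an independent mixed-model implementation", {
  set.seed(41)
  for (k in 1:20) {
    recs <- mk_timing()
    f <- fit_site_timing(recs)
    ref <- suppressMessages(lme4::lmer(
      doy ~ 0 + site + (1 | individual_id),
      data = recs, REML = TRUE
    ))
    expect_equal(unname(f$estimates$marginal_mean), unname(lme4::fixef(ref)),
      tolerance = 1e-6
    )
    expect_equal(unname(f$estimates$se),
      unname(sqrt(diag(as.matrix(vcov(ref))))),
      tolerance = 1e-6
    )
  }
})

test_that("with one record per individual the fit collapses to group means", {
  set.seed(42)
  recs <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:12),
    site = rep(c("A", "B"), each = 6),
    doy = c(120 + rnorm(6, 0, 2), 140 + rnorm(6, 0, 2))
  )
  f <- fit_site_timing(recs)
  means <- tapply(recs$doy, recs$site, mean)
  expect_equal(unname(f$estimates$marginal_mean), as.numeric(means), tolerance = 1e-6)
  # SE is the pooled residual sd over sqrt(n)
  pooled <- sqrt(sum((recs$doy - means[recs$site])^2) / (12 - 2))
  expect_equal(unname(f$estimates$se), rep(pooled / sqrt(6), 2), tolerance = 1e-6)
})

test_that("duplicating every record barely moves the marginal means", {
  # the duplicated data carry the same information; REML re-estimates the
  # variance ratio, so the GLS weights (and hence the means) can move by a
  # small fraction of a day but no more
  set.seed(43)
  recs <- mk_timing()
  f1 <- fit_site_timing(recs)
  f2 <- fit_site_timing(dplyr::bind_rows(recs, recs))
  expect_equal(f2$estimates$marginal_mean, f1$estimates$marginal_mean,
    tolerance = 0.005
  )
})

test_that("a single site falls back to the plain mean with a warning", {
  recs <- tibble::tibble(
    individual_id = c("a", "b", "c"), site = "only", doy = c(100, 104, 108)
  )
  expect_warning(f <- fit_site_timing(recs), "single site")
  expect_equal(f$estimates$marginal_mean, 104)
})

test_that("latitude regression matches the closed-form normal equations on printed site means", {
  # three breeding-arrival site means (published values used as inputs)
  est <- tibble::tibble(
    latitude = c(39.2, 41.38, 43.03),
    marginal_mean = c(107.1, 121.2, 127.0)
  )
  reg <- latitude_regression(est)
  x <- est$latitude
  y <- est$marginal_mean
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(reg$slope_days_per_deg, slope_oracle, tolerance = 1e-12)
  expect_equal(reg$intercept, mean(y) - slope_oracle * mean(x), tolerance = 1e-12)
  # collinear points give R^2 = 1 (summary.lm warns about the perfect fit)
  col <- tibble::tibble(latitude = 31:35, marginal_mean = 2 * (31:35) + 7)
  expect_equal(suppressWarnings(latitude_regression(col))$r_squared, 1)
  # adding a constant changes only the intercept
  shifted <- est
  shifted$marginal_mean <- shifted$marginal_mean + 11
  reg2 <- latitude_regression(shifted)
  expect_equal(reg2$slope_days_per_deg, reg$slope_days_per_deg)
  expect_equal(reg2$intercept, reg$intercept + 11)
  expect_error(latitude_regression(est[1:2, ]), "3 sites")
})

test_that("slope homogeneity finds equal slopes equal and different slopes different", {
  a <- tibble::tibble(latitude = c(32, 36, 40, 44), marginal_mean = 10 + 3 * c(32, 36, 40, 44))
  b <- tibble::tibble(latitude = c(32, 36, 40, 44), marginal_mean = 25 + 3 * c(32, 36, 40, 44))
  same <- suppressWarnings(slope_homogeneity(a, b)) # noiseless: perfect fit
  expect_lt(abs(same$interaction_estimate), 1e-10)
  set.seed(44)
  b2 <- tibble::tibble(
    latitude = c(32, 36, 40, 44),
    marginal_mean = 25 + 8 * c(32, 36, 40, 44) + rnorm(4, 0, 0.05)
  )
  diff5 <- slope_homogeneity(a, b2)
  expect_equal(diff5$interaction_estimate, 5, tolerance = 0.05)
  expect_lt(diff5$p_value, 0.01)
  # swapping the series flips the sign
  flipped <- slope_homogeneity(b2, a)
  expect_equal(flipped$interaction_estimate, -diff5$interaction_estimate)
})

test_that("tail alignment shifts the reference mean onto the new earliest date", {
  expect_equal(tail_align_estimate(c(5, 6, 7), 10)$estimate, 11)
  ref <- c(100, 103, 104, 106, 112)
  expect_equal(tail_align_estimate(ref, min(ref))$estimate, mean(ref))
  est <- tail_align_estimate(ref, 120)
  expect_equal(est$reference_span, 12)
  expect_equal(est$estimate - 120, mean(ref) - min(ref))
  # equivariance under a common shift
  for (k in c(-7, 13)) {
    expect_equal(tail_align_estimate(ref + k, 120 + k)$estimate,
                 est$estimate + k)
  }
  expect_error(tail_align_estimate(c(1, 2), 5), ">= 3")
})

test_that("the cumulative-fraction arrival rule behaves on elementary inputs", {
  # one observation per day over days 1..100: 2% reached on day 2
  d <- tibble::tibble(latitude_bin = 40, doy = 1:100, n_reporting = 1L)
  expect_equal(arrival_from_observations(d)$arrival_doy, 2)
  # all observations on one day
  d2 <- tibble::tibble(latitude_bin = 40, doy = 1:100,
                       n_reporting = c(rep(0L, 49), 500L, rep(0L, 50)))
  expect_equal(arrival_from_observations(d2)$arrival_doy, 50)
  # invariant to scaling all counts
  d3 <- tibble::tibble(latitude_bin = 40, doy = 1:100,
                       n_reporting = rpois(100, 1:100 / 10))
  a1 <- arrival_from_observations(d3)$arrival_doy
  d3$n_reporting <- d3$n_reporting * 13L
  expect_equal(arrival_from_observations(d3)$arrival_doy, a1)
  # zero counts everywhere is a no-data error
  d4 <- tibble::tibble(latitude_bin = 40, doy = 1:100, n_reporting = 0L)
  expect_error(arrival_from_observations(d4), "no observations")
})

test_that("arrival estimates track the scripted latitudinal gradient", {
  p <- obs_ramp_params(daily_effort = 200, years = 5, seed = 45)
  est <- arrival_from_observations(sim_observation_records(p))
  truth <- attr(sim_observation_records(p), "truth")
  j <- dplyr::left_join(est, truth, by = "latitude_bin")
  expect_true(all(diff(j$arrival_doy) > 0)) # monotone in bin latitude
  slope_est <- coef(lm(arrival_doy ~ latitude_bin, data = j))[2]
  slope_true <- coef(lm(true_arrival_doy ~ latitude_bin, data = j))[2]
  expect_lt(abs(slope_est - slope_true) / slope_true, 0.2)
  expect_true(all(j$n_years == 5))
})
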