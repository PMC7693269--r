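#' Site-level marginal mean event dates (random-intercept model)
#'
#' Fits `doy = site + (1 | individual) + error` by restricted maximum
#' likelihood: some individuals are tracked in more than one year, and the
#' random intercept keeps them from counting as independent birds. The
#' variance-ratio (individual / residual) is profiled out and optimized by
#' bounded scalar search; marginal means are the site fixed effects under
#' cell-means coding, with standard errors from the fixed-effect
#' covariance.
#'
#' @param records Tibble with `individual_id`, `site`, `doy` (one row per
#'   tracked year), e.g. one event's column gathered across individuals.
#' @param event_name Optional label carried into the output.
#' @return A `timing_lmm` object; its `estimates` element is the tibble of
#'   per-site `marginal_mean`, `se`, `n`.
#' @export
fit_site_timing <- function(records, event_name = NA_character_) {
  .check_cols(records, c("individual_id", "site", "doy"), "timing records")
  records <- records[!is.na(records$doy), ]
  sites <- sort(unique(records$site))
  if (length(sites) < 2) {
    rlang::warn("single site: returning the plain mean")
    est <- tibble::tibble(
      site = sites, event_name = event_name,
      marginal_mean = mean(records$doy),
      se = sd(records$doy) / sqrt(nrow(records)),
      n = nrow(records)
    )
    return(structure(
      list(
        estimates = est, lambda = 0, sigma2 = var(records$doy),
        sigma2_individual = 0, reml = NA_real_, records = records
      ),
      class = "timing_lmm"
    ))
  }
  .assert(nrow(records) >= 3, "need at least 3 records")
  y <- records$doy
  n <- length(y)
  X <- sapply(sites, function(s) as.numeric(records$site == s))
  ids <- unique(records$individual_id)
  Z <- sapply(ids, function(id) as.numeric(records$individual_id == id))
  p <- ncol(X)

  profile <- function(log_lambda) {
    lam <- exp(log_lambda)
    V0 <- diag(n) + lam * tcrossprod(Z)
    L <- t(chol(V0))
    Xh <- forwardsolve(L, X) # L^{-1} X, so crossprod gives X' V0^{-1} X
    yh <- forwardsolve(L, y)
    XtViX <- crossprod(Xh)
    beta <- solve(XtViX, crossprod(Xh, yh))
    rh <- yh - Xh %*% beta
    rss <- drop(crossprod(rh))
    logdetV <- 2 * sum(log(diag(L)))
    crit <- logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
      (n - p) * log(rss)
    list(crit = drop(crit), beta = drop(beta), XtViX = XtViX, rss = rss)
  }
  opt <- optimize(function(ll) profile(ll)$crit,
    interval = c(-12, 12), tol = 1e-10
  )
  # compare against the no-random-effect boundary
  at_zero <- profile(-Inf)
  best_ll <- if (at_zero$crit <= opt$objective) -Inf else opt$minimum
  fit <- profile(best_ll)
  lambda <- exp(best_ll)
  sigma2 <- fit$rss / (n - p)
  se <- sqrt(diag(solve(fit$XtViX)) * sigma2)
  est <- tibble::tibble(
    site = sites, event_name = event_name,
    marginal_mean = fit$beta, se = se,
    n = as.integer(table(records$site)[sites])
  )
  structure(
    list(
      estimates = est, lambda = lambda, sigma2 = sigma2,
      sigma2_individual = lambda * sigma2,
      reml = fit$crit, records = records
    ),
    class = "timing_lmm"
  )
}

#' @export
print.timing_lmm <- function(x, ...) {
  cat("Random-intercept timing model (REML)\n")
  cat(sprintf(
    "  residual SD %.3f d, individual SD %.3f d\n",
    sqrt(x$sigma2), sqrt(x$sigma2_individual)
  ))
  print(x$estimates)
  invisible(x)
}

#' Regression of site timing on latitude
#'
#' Ordinary least squares of marginal mean event date on site latitude:
#' the slope (days per degree) is the pace of the timing gradient.
#'
#' @param estimates Tibble with `latitude` and `marginal_mean` columns
#'   (>= 3 sites).
#' @return One-row tibble: `slope_days_per_deg`, `intercept`, `r_squared`,
#'   `p_value`, `n_sites`; the `lm` fit as attribute `"fit"`.
#' @export
latitude_regression <- function(estimates) {
  .check_cols(estimates, c("latitude", "marginal_mean"), "timing estimates")
  .assert(nrow(estimates) >= 3, "need at least 3 sites")
  fit <- lm(marginal_mean ~ latitude, data = estimates)
  sm <- summary(fit)
  out <- tibble::tibble(
    slope_days_per_deg = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_sites = nrow(estimates)
  )
  attr(out, "fit") <- fit
  out
}

#' Are two latitude-timing slopes the same?
#'
#' Pools two series of timing estimates (e.g. breeding-site arrival and
#' nest initiation) and fits
#' `mean ~ category * latitude`; the interaction coefficient estimates
#' the slope difference (series b minus series a) and its t-test is the
#' homogeneity test.
#'
#' @param series_a,series_b Tibbles with `latitude`, `marginal_mean`
#'   (>= 3 points each).
#' @param labels Length-2 labels for the two series.
#' @return One-row tibble: `interaction_estimate` (days/degree), `se`,
#'   `p_value`.
#' @export
slope_homogeneity <- function(series_a, series_b,
                              labels = c("series_a", "series_b")) {
  .check_cols(series_a, c("latitude", "marginal_mean"), "series a")
  .check_cols(series_b, c("latitude", "marginal_mean"), "series b")
  .assert(nrow(series_a) >= 3 && nrow(series_b) >= 3,
          "each series needs at least 3 points")
  pooled <- dplyr::bind_rows(
    dplyr::mutate(series_a[, c("latitude", "marginal_mean")], category = labels[1]),
    dplyr::mutate(series_b[, c("latitude", "marginal_mean")], category = labels[2])
  )
  pooled$category <- factor(pooled$category, levels = labels)
  fit <- lm(marginal_mean ~ category * latitude, data = pooled)
  sm <- summary(fit)$coefficients
  row <- grep(":latitude", rownames(sm))
  .assert(length(row) == 1 && !any(is.na(coef(fit))), "degenerate design")
  tibble::tibble(
    interaction_estimate = sm[row, 1],
    se = sm[row, 2],
    p_value = sm[row, 4]
  )
}

#' Estimate mean timing by aligning distribution tails
#'
#' Historical studies often report only the earliest observed date. Given
#' a well-sampled reference distribution of the same event, the mean is
#' estimated by sliding the reference so its left tail (its minimum, by
#' default) sits on the reported earliest date:
#' `estimate = earliest_new + (mean(ref) - tail(ref))`.
#'
#' @param reference Numeric sample of event days from the reference site
#'   (>= 3 values).
#' @param earliest_new Earliest date (day of year) reported by the study
#'   being estimated.
#' @param tail_def `"minimum"` (default) or `"p2.5"` (2.5th percentile of
#'   a fitted normal).
#' @return One-row tibble: `estimate`, `offset`, `reference_span`,
#'   `reference_n`.
#' @export
tail_align_estimate <- function(reference, earliest_new,
                                tail_def = c("minimum", "p2.5")) {
  .assert(length(reference) >= 3, "reference sample must have >= 3 values")
  tail_def <- match.arg(tail_def)
  left <- switch(tail_def,
    minimum = min(reference),
    p2.5 = mean(reference) + qnorm(0.025) * sd(reference)
  )
  offset <- mean(reference) - left
  tibble::tibble(
    estimate = earliest_new + offset,
    offset = offset,
    reference_span = max(reference) - min(reference),
    reference_n = length(reference)
  )
}

#' Arrival date from observation frequencies (cumulative-fraction rule)
#'
#' Mean arrival in a latitude bin is the first day on which the cumulative
#' count of reported observations reaches `fraction` (2 percent by
#' default) of the bin's seasonal total; per-year estimates are averaged
#' and their spread gives a between-year standard error.
#'
#' @param counts Tibble with `latitude_bin`, `doy`, `n_reporting` and
#'   optionally `year` (from [sim_observation_records()] or real data).
#' @param fraction Cumulative fraction defining arrival.
#' @param season_window Optional `c(start, end)` day-of-year window.
#' @return A tibble per bin: `latitude_bin`, `arrival_doy`, `se`,
#'   `n_years`, `total_count`.
#' @export
arrival_from_observations <- function(counts, fraction = 0.02,
                                      season_window = NULL) {
  .check_cols(counts, c("latitude_bin", "doy", "n_reporting"), "observation counts")
  if (!is.null(season_window)) {
    counts <- counts[counts$doy >= season_window[1] & counts$doy <= season_window[2], ]
  }
  if (!"year" %in% names(counts)) counts$year <- 1L
  per_year <- counts |>
    dplyr::group_by(.data$latitude_bin, .data$year) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      total <- sum(df$n_reporting)
      if (total == 0) return(tibble::tibble(arrival_doy = NA_real_, total = 0))
      cum <- cumsum(df$n_reporting) / total
      tibble::tibble(
        arrival_doy = df$doy[which(cum >= fraction)[1]],
        total = total
      )
    }) |>
    dplyr::ungroup()
  out <- per_year |>
    dplyr::group_by(.data$latitude_bin) |>
    dplyr::summarise(
      mean_arrival = mean(.data$arrival_doy, na.rm = TRUE),
      se = sd(.data$arrival_doy, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$arrival_doy))),
      n_years = sum(!is.na(.data$arrival_doy)),
      total_count = sum(.data$total),
      .groups = "drop"
    ) |>
    dplyr::rename(arrival_doy = "mean_arrival")
  .assert(any(out$total_count > 0), "no observations in the season window")
  if (any(out$total_count == 0)) {
    rlang::warn("some bins have zero observations; arrival is NA there")
    out$arrival_doy[out$total_count == 0] <- NA_real_
  }
  out
}
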