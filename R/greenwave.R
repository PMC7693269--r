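#' Standardize biomass to phenological stage
#'
#' Seasonal biomass varies by an order of magnitude across studies and
#' latitudes, so absolute values are not comparable. Each study's
#' measurements are rescaled by its within-study seasonal maximum of mean
#' standing biomass: `stage = mean / max(mean)`, a 0--1 green-up fraction
#' (the maximal observation maps to 1 by construction; noisy values may
#' slightly exceed 1 elsewhere and are deliberately not clipped).
#' Standard errors scale alongside, and the inverse-variance weight
#' `1 / stage_se^2` carries each observation's precision into the model.
#'
#' @param observations Tibble with `study_id`, `latitude`, `doy`,
#'   `biomass_mean`, `biomass_se`, `n` (see [sim_biomass_studies()]).
#' @return A tibble of standardized observations: input keys plus `stage`,
#'   `stage_se`, `weight`.
#' @export
standardize_biomass <- function(observations) {
  .check_cols(observations,
    c("study_id", "latitude", "doy", "biomass_mean", "biomass_se"),
    "biomass observations"
  )
  .assert(all(observations$biomass_se > 0), "biomass_se must be > 0")
  observations |>
    dplyr::group_by(.data$study_id) |>
    dplyr::group_modify(function(df, key) {
      .assert(nrow(df) >= 2, paste0("study ", key$study_id, " has fewer than 2 observations"))
      total <- max(df$biomass_mean)
      .assert(total > 0, paste0("study ", key$study_id, " has zero seasonal total"))
      df$stage <- df$biomass_mean / total
      df$stage_se <- df$biomass_se / total
      df$weight <- 1 / df$stage_se^2
      df
    }) |>
    dplyr::ungroup()
}

#' Fit the green-wave model (weighted GEE with AR(1) correlation)
#'
#' Fits the linear mean model
#' \deqn{stage = \beta_0 + \beta_d \, doy + \beta_l \, lat + \beta_{dl} \, doy \cdot lat}
#' on the 0--1 stage scale (identity link) by generalized estimating
#' equations: observations are inverse-variance weighted, repeated
#' measures within a study share an AR(1) working correlation (by visit
#' order), and the fit alternates weighted generalized least squares with
#' moment re-estimation of the correlation until the coefficients move by
#' less than `tol`. Standard errors are robust (sandwich) by default;
#' model-based standard errors are also stored.
#'
#' @param std Standardized observations from [standardize_biomass()]
#'   (columns `study_id`, `latitude`, `doy`, `stage`, `weight`).
#' @param rho Fix the AR(1) correlation at this value instead of
#'   estimating it (`NULL`, the default, estimates it).
#' @param tol Convergence tolerance on the coefficients.
#' @param max_iter Maximum number of GLS / moment iterations.
#' @return A `greenwave_gee` object: coefficients, robust and model-based
#'   covariances, `rho`, scale `phi`, iteration count and the data used.
#' @export
fit_greenwave <- function(std, rho = NULL, tol = 1e-8, max_iter = 50) {
  .check_cols(std, c("study_id", "latitude", "doy", "stage", "weight"), "standardized data")
  .assert(length(unique(std$study_id)) >= 2, "need at least 2 studies")
  .assert(nrow(std) >= 6, "need at least 6 observations")
  .assert(all(std$weight > 0), "weights must be > 0")
  std <- dplyr::arrange(std, .data$study_id, .data$doy)
  # centre covariates for conditioning; coefficients are mapped back below
  m_doy <- mean(std$doy)
  m_lat <- mean(std$latitude)
  dc <- std$doy - m_doy
  lc <- std$latitude - m_lat
  X <- cbind(
    intercept = 1, doy = dc, latitude = lc,
    doy_latitude = dc * lc
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    rlang::abort(paste0(
      "singular design: ", paste(bad, collapse = ", "),
      " collinear with earlier terms (e.g. a single latitude)"
    ))
  }
  y <- std$stage
  w <- std$weight
  idx <- split(seq_len(nrow(std)), std$study_id)
  p <- ncol(X)
  N <- nrow(std)

  fixed_rho <- !is.null(rho)
  rho_hat <- if (fixed_rho) rho else 0
  beta <- rep(0, p)
  phi <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- matrix(0, p, p)
    u <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Ai_half <- 1 / sqrt(w[ii]) # per-observation SDs (up to scale phi)
      R <- rho_hat^abs(outer(seq_len(ni), seq_len(ni), "-"))
      Vi <- (Ai_half %o% Ai_half) * R
      Vinv <- solve(Vi)
      Xi <- X[ii, , drop = FALSE]
      B <- B + crossprod(Xi, Vinv %*% Xi)
      u <- u + crossprod(Xi, Vinv %*% y[ii])
    }
    beta_new <- drop(solve(B, u))
    # standardized residuals and moment updates
    r_std <- sqrt(w) * (y - drop(X %*% beta_new))
    phi <- sum(r_std^2) / (N - p)
    if (!fixed_rho) {
      num <- 0
      npairs <- 0
      for (ii in idx) {
        ri <- r_std[ii]
        if (length(ri) > 1) {
          num <- num + sum(ri[-1] * ri[-length(ri)])
          npairs <- npairs + length(ri) - 1
        }
      }
      rho_hat <- if (npairs > p) num / ((npairs - p) * phi) else 0
      rho_hat <- max(min(rho_hat, 0.99), -0.99)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::abort(paste0(
      "GEE did not converge in ", max_iter,
      " iterations (last max coefficient change ", signif(delta, 3), ")"
    ))
  }
  # final information and sandwich pieces at the converged estimates
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ai_half <- 1 / sqrt(w[ii])
    R <- rho_hat^abs(outer(seq_len(ni), seq_len(ni), "-"))
    Vinv <- solve((Ai_half %o% Ai_half) * R)
    Xi <- X[ii, , drop = FALSE]
    ri <- y[ii] - drop(Xi %*% beta)
    B <- B + crossprod(Xi, Vinv %*% Xi)
    s <- crossprod(Xi, Vinv %*% ri)
    M <- M + s %*% t(s)
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  vcov_model <- phi * Binv
  # map centred-scale coefficients back to the raw (doy, latitude) scale
  A <- rbind(
    c(1, -m_doy, -m_lat, m_doy * m_lat),
    c(0, 1, 0, -m_lat),
    c(0, 0, 1, -m_doy),
    c(0, 0, 0, 1)
  )
  beta <- drop(A %*% beta)
  vcov_robust <- A %*% vcov_robust %*% t(A)
  vcov_model <- A %*% vcov_model %*% t(A)
  names(beta) <- colnames(X)
  dimnames(vcov_robust) <- dimnames(vcov_model) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = beta,
      vcov_robust = vcov_robust,
      vcov_model = vcov_model,
      rho = rho_hat,
      rho_fixed = fixed_rho,
      phi = phi,
      n_obs = N,
      n_studies = length(idx),
      iterations = iter,
      data = std
    ),
    class = "greenwave_gee"
  )
}

#' @export
print.greenwave_gee <- function(x, ...) {
  cat("Green-wave GEE (identity link, AR(1) working correlation)\n")
  cat(sprintf(
    "  %d observations, %d studies; rho = %.3f%s, scale = %.4g\n",
    x$n_obs, x$n_studies, x$rho, if (x$rho_fixed) " (fixed)" else "", x$phi
  ))
  tab <- cbind(
    estimate = x$coefficients,
    robust_se = sqrt(diag(x$vcov_robust)),
    model_se = sqrt(diag(x$vcov_model))
  )
  print(round(tab, 6))
  invisible(x)
}

#' Coefficient standard errors of a green-wave fit
#'
#' @param model A `greenwave_gee` object.
#' @param se_type `"robust"` (sandwich, default) or `"model"`.
#' @return Named numeric vector of standard errors.
#' @export
greenwave_se <- function(model, se_type = c("robust", "model")) {
  se_type <- match.arg(se_type)
  V <- if (se_type == "robust") model$vcov_robust else model$vcov_model
  sqrt(diag(V))
}

#' Predict phenological stage
#'
#' Evaluates the fitted linear predictor on the stage (0--1 fraction)
#' scale; multiply by 100 for percent of seasonal maximum.
#'
#' @param model A `greenwave_gee` fit.
#' @param doy Day(s) of year.
#' @param latitude Degrees (recycled against `doy`).
#' @return Stage fractions.
#' @export
predict_stage <- function(model, doy, latitude) {
  b <- model$coefficients
  b[["intercept"]] + b[["doy"]] * doy + b[["latitude"]] * latitude +
    b[["doy_latitude"]] * doy * latitude
}

#' Date at which a target stage is reached
#'
#' Inverts the fitted linear model at a given latitude:
#' `doy = (target - b0 - b_lat * lat) / (b_doy + b_dl * lat)`.
#'
#' @param model A `greenwave_gee` fit.
#' @param target_stage Stage fraction to solve for.
#' @param latitude Degrees (vectorized).
#' @return Day of year (possibly fractional).
#' @export
stage_date <- function(model, target_stage, latitude) {
  b <- model$coefficients
  slope <- b[["doy"]] + b[["doy_latitude"]] * latitude
  .assert(all(abs(slope) > 1e-12), "zero date-slope at this latitude; cannot invert")
  (target_stage - b[["intercept"]] - b[["latitude"]] * latitude) / slope
}

#' Phenological stage at nest initiation, by site
#'
#' Predicts the stage of seasonal biomass accumulation at each
#' individual's nest-initiation date, summarizes per-site means, and
#' tests stage homogeneity across sites with a Kruskal--Wallis rank test
#' (individuals without a nest date are skipped with a message).
#'
#' @param model A `greenwave_gee` fit.
#' @param events Event tibble with `individual_id`, `site`,
#'   `nest_initiation` (day of year).
#' @param site_latitudes Named vector or tibble (`site`, `latitude`)
#'   giving each site's latitude.
#' @return A list: `individuals` (per-bird predicted stages),
#'   `by_site` (site means), `mean_stage` (grand mean), and
#'   `homogeneity` (statistic, df, p_value).
#' @export
stage_at_events <- function(model, events, site_latitudes) {
  .check_cols(events, c("individual_id", "site", "nest_initiation"), "events")
  if (is.data.frame(site_latitudes)) {
    site_latitudes <- setNames(site_latitudes$latitude, site_latitudes$site)
  }
  miss <- is.na(events$nest_initiation)
  if (any(miss)) {
    message(sum(miss), " individual(s) without a nest date skipped")
    events <- events[!miss, ]
  }
  .assert(nrow(events) > 0, "no nest dates available")
  ind <- events |>
    dplyr::mutate(
      latitude = unname(site_latitudes[.data$site]),
      stage = predict_stage(model, .data$nest_initiation, .data$latitude)
    ) |>
    dplyr::select(dplyr::all_of(c("individual_id", "site", "latitude",
                                  "nest_initiation", "stage")))
  by_site <- ind |>
    dplyr::group_by(.data$site, .data$latitude) |>
    dplyr::summarise(
      mean_stage = mean(.data$stage), sd_stage = sd(.data$stage),
      n = dplyr::n(), .groups = "drop"
    )
  homo <- if (length(unique(ind$site)) >= 2 && stats::var(ind$stage) > 0) {
    kt <- kruskal.test(ind$stage, factor(ind$site))
    tibble::tibble(
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value
    )
  } else {
    tibble::tibble(
      statistic = 0, df = max(0, length(unique(ind$site)) - 1), p_value = 1
    )
  }
  list(
    individuals = ind, by_site = by_site,
    mean_stage = mean(ind$stage), homogeneity = homo
  )
}
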