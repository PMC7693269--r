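#' Tidy a green-wave GEE fit
#'
#' @param x A `greenwave_gee` object.
#' @param se_type `"robust"` or `"model"` standard errors.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy greenwave_gee
#' @export
tidy.greenwave_gee <- function(x, se_type = c("robust", "model"), ...) {
  se <- greenwave_se(x, match.arg(se_type))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname tidy.greenwave_gee
#' @method glance greenwave_gee
#' @export
glance.greenwave_gee <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, phi = x$phi, n_obs = x$n_obs,
    n_studies = x$n_studies, iterations = x$iterations
  )
}

#' Tidy a random-intercept timing fit
#'
#' @param x A `timing_lmm` object.
#' @param ... Unused.
#' @return The per-site marginal means as a tibble (`site`, `event_name`,
#'   `marginal_mean`, `se`, `n`).
#' @method tidy timing_lmm
#' @export
tidy.timing_lmm <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.timing_lmm
#' @method glance timing_lmm
#' @export
glance.timing_lmm <- function(x, ...) {
  tibble::tibble(
    sigma_residual = sqrt(x$sigma2),
    sigma_individual = sqrt(x$sigma2_individual),
    lambda = x$lambda,
    n = nrow(x$records)
  )
}

#' Tidy a maximally selected cutpoint result
#'
#' @param x A `maxstat_cutpoint` object.
#' @param ... Unused.
#' @return One-row tibble: `cutpoint`, `t_max`, `p_perm`, group means/ns.
#' @method tidy maxstat_cutpoint
#' @export
tidy.maxstat_cutpoint <- function(x, ...) {
  tibble::tibble(
    cutpoint = x$cutpoint, t_max = x$t_max, p_perm = x$p_perm,
    mean_below = x$group_means[["below"]],
    mean_above = x$group_means[["above"]],
    n_below = x$group_n[["below"]],
    n_above = x$group_n[["above"]]
  )
}
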