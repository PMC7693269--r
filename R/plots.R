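#' Plot a degree-day climatology and its jerk
#'
#' @param object A tibble from [gdd_jerk()].
#' @param ... Unused.
#' @return A ggplot: cumulative degree days (top) and jerk (bottom),
#'   faceted.
#' @method autoplot marshwave_jerk
#' @export
autoplot.marshwave_jerk <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("doy", "cum_gdd", "jerk")],
    cols = c("cum_gdd", "jerk"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$doy, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "day of year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a green-wave fit over the standardized observations
#'
#' Stage observations coloured by latitude with fitted lines per study
#' latitude.
#'
#' @param object A `greenwave_gee` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot greenwave_gee
#' @export
autoplot.greenwave_gee <- function(object, ...) {
  d <- object$data
  lats <- sort(unique(d$latitude))
  pred <- tidyr::expand_grid(
    latitude = lats,
    doy = seq(min(d$doy), max(d$doy), length.out = 50)
  )
  pred$stage <- predict_stage(object, pred$doy, pred$latitude)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$doy, y = .data$stage, colour = .data$latitude,
    group = .data$latitude
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = pred) +
    ggplot2::scale_colour_viridis_c(name = "latitude (°N)") +
    ggplot2::labs(
      x = "day of year",
      y = "stage (fraction of seasonal maximum biomass)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cutpoint search profile
#'
#' Standardized statistic against candidate cutpoint, with the selected
#' cutpoint marked.
#'
#' @param object A `maxstat_cutpoint` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot maxstat_cutpoint
#' @export
autoplot.maxstat_cutpoint <- function(object, ...) {
  ggplot2::ggplot(
    object$candidates,
    ggplot2::aes(x = .data$cutpoint, y = .data$statistic)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = 2) +
    ggplot2::labs(
      x = "candidate cutpoint", y = "standardized statistic",
      title = sprintf(
        "T_max = %.3f at %.3g (perm. p = %.3g)",
        object$t_max, object$cutpoint, object$p_perm
      )
    ) +
    ggplot2::theme_minimal()
}

#' Nest date against the two phenological indicators (1:1 plot)
#'
#' @param results A `marshwave_results` bundle.
#' @return A ggplot of per-site nest date against each indicator date,
#'   with the 1:1 line.
#' @export
plot_indicator_match <- function(results) {
  long <- tidyr::pivot_longer(
    results$fig3,
    cols = c("onset_doy", "stage_date_doy"),
    names_to = "indicator", values_to = "indicator_doy"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$indicator_doy, y = .data$nest_doy,
    colour = .data$site, shape = .data$indicator
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "phenological indicator date (day of year)",
      y = "mean nest initiation (day of year)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
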