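#' Parameters for synthetic observation-frequency ramps
#'
#' Emulates citizen-science checklist frequencies by latitude bin: the
#' expected proportion of checklists reporting the species rises along a
#' logistic ramp as migrants arrive, and daily reporting counts are Poisson
#' around `daily_effort` times that proportion. The ramp for each bin is
#' centred so that the day at which the *noise-free* cumulative curve first
#' reaches `arrival_fraction` of its seasonal total equals the bin's true
#' arrival day — so the cumulative-fraction estimator has an exact target.
#'
#' @param latitude_bins Bin-centre latitudes, degrees.
#' @param true_arrival_doy True arrival day of year per bin.
#' @param ramp_steepness Logistic steepness, per day.
#' @param plateau Late-season reporting proportion (ramp asymptote).
#' @param season_window Length-2 `c(start, end)` days of year bounding the
#'   season over which totals are accumulated.
#' @param daily_effort Expected checklists per day per bin.
#' @param years Number of independent seasons (years) simulated.
#' @param arrival_fraction Cumulative fraction defining "arrival" (the
#'   2 percent rule by default).
#' @param seed Integer seed.
#' @return An `obs_ramp_params` list.
#' @export
obs_ramp_params <- function(latitude_bins = seq(32.5, 44.5, by = 2),
                            true_arrival_doy = 80 + 2.5 * (seq(32.5, 44.5, by = 2) - 32.5),
                            ramp_steepness = 0.25,
                            plateau = 0.25,
                            season_window = c(32, 212),
                            daily_effort = 50,
                            years = 10,
                            arrival_fraction = 0.02,
                            seed = 1L) {
  .assert(length(true_arrival_doy) == length(latitude_bins),
          "one true arrival per latitude bin")
  .assert(all(true_arrival_doy > season_window[1] & true_arrival_doy < season_window[2]),
          "arrival dates must lie inside the season window")
  .assert(daily_effort > 0, "effort must be > 0")
  .assert(diff(season_window) > 20 / ramp_steepness,
          "season window shorter than the ramp support")
  structure(
    list(
      latitude_bins = latitude_bins,
      true_arrival_doy = true_arrival_doy,
      ramp_steepness = ramp_steepness,
      plateau = plateau,
      season_window = season_window,
      daily_effort = daily_effort,
      years = as.integer(years),
      arrival_fraction = arrival_fraction,
      seed = as.integer(seed)
    ),
    class = "obs_ramp_params"
  )
}

# day at which the cumulative noise-free ramp first reaches `fraction`,
# for a logistic ramp centred at `centre`
.ramp_arrival <- function(centre, k, window, fraction) {
  doy <- seq(window[1], window[2])
  p <- 1 / (1 + exp(-k * (doy - centre)))
  cum <- cumsum(p) / sum(p)
  doy[which(cum >= fraction)[1]]
}

# solve for the ramp centre that puts the cumulative-fraction day at target
.ramp_centre <- function(target, k, window, fraction) {
  f <- function(centre) .ramp_arrival(centre, k, window, fraction) - target
  lo <- window[1]
  hi <- window[2]
  # .ramp_arrival is monotone non-decreasing in centre; bisect on integers
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' Simulate daily observation-frequency records
#'
#' @param params An [obs_ramp_params()] object.
#' @return A tibble with `year`, `latitude_bin`, `doy`, `n_reporting` and
#'   the per-bin ground truth as attribute `"truth"` (tibble of
#'   `latitude_bin`, `true_arrival_doy`).
#' @export
sim_observation_records <- function(params) {
  .assert(inherits(params, "obs_ramp_params"), "params must come from obs_ramp_params()")
  p <- params
  doy <- seq(p$season_window[1], p$season_window[2])
  centres <- vapply(
    p$true_arrival_doy,
    function(a) .ramp_centre(a, p$ramp_steepness, p$season_window, p$arrival_fraction),
    numeric(1)
  )
  out <- .with_seed(p$seed, {
    purrr::map_dfr(seq_len(p$years), function(yr) {
      purrr::map_dfr(seq_along(p$latitude_bins), function(i) {
        prop <- p$plateau / (1 + exp(-p$ramp_steepness * (doy - centres[i])))
        tibble::tibble(
          year = yr,
          latitude_bin = p$latitude_bins[i],
          doy = doy,
          n_reporting = rpois(length(doy), p$daily_effort * prop)
        )
      })
    })
  })
  attr(out, "truth") <- tibble::tibble(
    latitude_bin = p$latitude_bins,
    true_arrival_doy = p$true_arrival_doy
  )
  out
}
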