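#' Published eastern willet annual-cycle timing table
#'
#' Site-group marginal mean days of year for the five annual-cycle stages
#' of the eastern willet, transcribed from a published geolocator study of
#' breeding sites in New Jersey (39.2 deg N), southern Massachusetts
#' (41.38 deg N) and northern Massachusetts / Maine (43.03 deg N). Winter
#' arrival uses the all-individuals values (including birds that flew
#' nonstop to the wintering grounds). The reference (southernmost) site is
#' the first mean column, as [timing_difference_summary()] expects.
#'
#' @return A tibble with columns `stage`, `nj`, `ma_south`, `ma_north_me`.
#' @export
willet_timing_table <- function() {
  path <- system.file("extdata", "willet_annual_cycle_timing.csv",
    package = "marshwave", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
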