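Package: marshwave
Title: Salt-Marsh Green-Wave Phenology and Shorebird Annual-Cycle Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking a latitudinal "green wave" of salt-marsh
    phenology to the annual-cycle timing of migratory shorebirds. Computes
    single-sine growing degree days, multi-year climatologies and the
    degree-day jerk (third derivative) spring-onset statistic; classifies
    light-level geolocator records into twilight times, threshold positions,
    transoceanic flights, incubation bouts and per-individual annual-cycle
    event tables; standardizes multi-study seasonal biomass to phenological
    stage and fits an inverse-variance weighted date-by-latitude model with
    an AR(1) working correlation; and provides timing estimators
    (random-intercept marginal means, latitude regressions, tail alignment,
    cumulative-fraction arrival dates, maximally selected cutpoints). A
    synthetic-data module generates all four input streams with known ground
    truth so the full pipeline can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
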