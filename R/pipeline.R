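#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic climate
#' and biomass worlds, the deployment sites and scripted schedules, the
#' degree-day settings, detection thresholds and the target phenological
#' stage. All randomness is derived from `seed`.
#'
#' The default world couples the streams the way the study system works:
#' each site's birds nest (with small individual jitter) on the day their
#' latitude's biomass green-up reaches `common_nest_stage` of its seasonal
#' maximum, so the scripted truth is a latitude-invariant phenological
#' stage that the fitted indicators should rediscover.
#'
#' @param seed Master integer seed.
#' @param climate A [climate_params()] block (noise off by default so the
#'   onset grid is smooth; set `noise_sd` for noisy runs).
#' @param biomass A [biomass_params()] block.
#' @param station_grid Latitudes of the coastal station grid, degrees.
#' @param sites Tibble of deployment sites: `site`, `latitude`,
#'   `longitude`, `n_individuals`.
#' @param common_nest_stage Stage fraction at which nests are scripted.
#' @param nest_jitter_days SD-like half-range of individual nest jitter
#'   (uniform integer on `-nest_jitter_days..nest_jitter_days`).
#' @param base_temp Degree-day base temperature, deg C.
#' @param smoothing_halfwidth,onset_window Passed to [gdd_jerk()] /
#'   [spring_onset()].
#' @param stage_window Stage fractions retained when fitting the
#'   green-wave model (the early green-up limb).
#' @param target_stage Stage used for indicator dates; `NULL` (default)
#'   derives it from the data as the mean predicted stage at nest
#'   initiation, mirroring how a common stage is defined in practice.
#' @param light_threshold,zenith,min_dry_hours,gap_days Detection settings.
#' @return A `marshwave_config` list.
#' @export
run_config <- function(seed = 1L,
                       climate = climate_params(noise_sd = 0, years = 1, seed = seed),
                       biomass = biomass_params(seed = seed + 1L),
                       station_grid = seq(32, 44, by = 1),
                       sites = tibble::tibble(
                         site = c("NJ", "MA_south", "MA_north_ME"),
                         latitude = c(39.27, 41.33, 43.03),
                         longitude = c(-75.24, -70.01, -70.65),
                         n_individuals = c(7L, 6L, 7L)
                       ),
                       common_nest_stage = 0.295,
                       nest_jitter_days = 1,
                       base_temp = 10,
                       smoothing_halfwidth = 20,
                       smoothing_passes = 3,
                       onset_window = c(1, 181),
                       stage_window = c(0.10, 0.50),
                       target_stage = NULL,
                       light_threshold = 1,
                       zenith = 96,
                       min_dry_hours = 20,
                       gap_days = 30) {
  structure(
    list(
      seed = as.integer(seed), climate = climate, biomass = biomass,
      station_grid = station_grid, sites = sites,
      common_nest_stage = common_nest_stage,
      nest_jitter_days = nest_jitter_days,
      base_temp = base_temp, smoothing_halfwidth = smoothing_halfwidth,
      smoothing_passes = smoothing_passes,
      onset_window = onset_window, stage_window = stage_window,
      target_stage = target_stage,
      light_threshold = light_threshold, zenith = zenith,
      min_dry_hours = min_dry_hours, gap_days = gap_days
    ),
    class = "marshwave_config"
  )
}

# script one site's individuals nesting at the scripted common stage
.script_site <- function(config, site_row, ids) {
  nest0 <- round(true_stage_date(
    config$biomass, config$common_nest_stage, site_row$latitude
  ))
  jit <- .with_seed(
    config$seed + 97L * match(site_row$site, config$sites$site),
    sample(seq(-config$nest_jitter_days, config$nest_jitter_days),
      length(ids),
      replace = TRUE
    )
  )
  purrr::map2(ids, jit, function(id, j) {
    nest <- nest0 + j
    track_script(
      individual_id = id, site = site_row$site,
      site_lat = site_row$latitude, site_lon = site_row$longitude,
      spring_departure = nest - 33, breeding_arrival = nest - 20,
      nest_initiation = nest, fall_departure = nest + 65,
      winter_arrival = nest + 88,
      seed = config$seed + 1000L + match(id, ids) +
        10000L * match(site_row$site, config$sites$site)
    )
  })
}

#' Run the full green-wave analysis end to end
#'
#' Simulates (or, with user-supplied tables, ingests) the four data
#' streams, runs every stage of the analysis, and returns the result
#' tables: per-individual and per-site event timing, the spring-onset
#' table over the station grid, the fitted green-wave model, the
#' nest-date-versus-indicator comparison per site (the 1:1 check), the
#' indicator-versus-indicator comparison across the latitude grid with
#' its cutpoint analysis, and a manifest recording the configuration.
#'
#' @param config A [run_config()] object.
#' @return A `marshwave_results` list: `events`, `site_timing`, `onsets`,
#'   `greenwave`, `stage_summary`, `target_stage`, `fig3` (per-site
#'   nest/indicator dates), `fig4` (per-latitude indicator dates,
#'   regression, `cutpoint`), `manifest`.
#' @export
run_greenwave_pipeline <- function(config = run_config()) {
  .assert(inherits(config, "marshwave_config"), "config must come from run_config()")
  stage_name <- ""
  run_stage <- function(name, expr) {
    stage_name <<- name
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # --- spring onset over the station grid ------------------------------
  onsets <- run_stage("degree_days", {
    purrr::map_dfr(config$station_grid, function(lat) {
      clim <- sim_climate(config$climate, lat,
        station_id = sprintf("st_%04.1f", lat)
      ) |>
        cumulative_gdd(base = config$base_temp) |>
        average_climatology()
      on <- spring_onset(
        gdd_jerk(clim,
          halfwidth = config$smoothing_halfwidth,
          passes = config$smoothing_passes
        ),
        window = config$onset_window
      )
      tibble::tibble(
        station_id = sprintf("st_%04.1f", lat), latitude = lat,
        onset_doy = on$onset_doy, jerk_value = on$jerk_value
      )
    })
  })
  onset_at <- function(lat) {
    stats::approx(onsets$latitude, onsets$onset_doy, xout = lat, rule = 2)$y
  }

  # --- green-wave model from the biomass studies -----------------------
  gw <- run_stage("greenwave_model", {
    std <- sim_biomass_studies(config$biomass) |> standardize_biomass()
    std_fit <- std[std$stage >= config$stage_window[1] &
      std$stage <= config$stage_window[2], ]
    fit_greenwave(std_fit)
  })

  # --- geolocator tracks and event detection ---------------------------
  events <- run_stage("geolocator_events", {
    purrr::map_dfr(seq_len(nrow(config$sites)), function(i) {
      row <- config$sites[i, ]
      ids <- sprintf("%s_%02d", row$site, seq_len(row$n_individuals))
      scripts <- .script_site(config, row, ids)
      purrr::map_dfr(scripts, function(sc) {
        tr <- sim_geolocator_track(sc)
        det <- detect_annual_cycle(tr,
          threshold = config$light_threshold, zenith = config$zenith,
          min_dry_hours = config$min_dry_hours, gap_days = config$gap_days
        )
        det$latitude <- row$latitude
        det$true_nest <- sc$events[["nest_initiation"]]
        det
      })
    })
  })

  # --- site-level timing -----------------------------------------------
  site_timing <- run_stage("timing_inference", {
    event_cols <- c(
      "spring_departure", "breeding_arrival", "nest_initiation",
      "fall_departure", "winter_arrival"
    )
    purrr::map_dfr(event_cols, function(evc) {
      recs <- tibble::tibble(
        individual_id = events$individual_id, site = events$site,
        doy = events[[evc]]
      )
      fit_site_timing(recs, event_name = evc)$estimates
    }) |>
      dplyr::left_join(config$sites[, c("site", "latitude")], by = "site")
  })

  # --- stage at nest initiation, target stage, indicator tables --------
  stage_summary <- run_stage("stage_at_events", {
    stage_at_events(
      gw, events[, c("individual_id", "site", "nest_initiation")],
      setNames(config$sites$latitude, config$sites$site)
    )
  })
  target <- config$target_stage %||% stage_summary$mean_stage

  fig3 <- run_stage("fig3_table", {
    nest_means <- site_timing[site_timing$event_name == "nest_initiation", ]
    nest_means |>
      dplyr::transmute(
        site = .data$site, latitude = .data$latitude,
        nest_doy = .data$marginal_mean,
        onset_doy = onset_at(.data$latitude),
        stage_date_doy = stage_date(gw, target, .data$latitude)
      )
  })

  fig4 <- run_stage("fig4_table", {
    grid <- tibble::tibble(
      latitude = config$station_grid,
      onset_doy = onsets$onset_doy,
      stage_date_doy = stage_date(gw, target, config$station_grid)
    )
    grid$deviation_days <- grid$onset_doy - grid$stage_date_doy
    reg <- lm(onset_doy ~ stage_date_doy, data = grid)
    cut <- if (nrow(grid) >= 10) {
      maxstat_cutpoint(grid,
        x = "latitude", y = "deviation_days",
        min_prop = 0.1, n_perm = 1999, seed = config$seed + 7L
      )
    } else {
      NULL
    }
    list(
      grid = grid,
      slope = unname(coef(reg)[2]),
      r_squared = summary(reg)$r.squared,
      cutpoint = cut
    )
  })

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_tracks = nrow(events),
    n_stations = nrow(onsets),
    target_stage = target,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  structure(
    list(
      events = events, site_timing = site_timing, onsets = onsets,
      greenwave = gw, stage_summary = stage_summary,
      target_stage = target, fig3 = fig3, fig4 = fig4,
      manifest = manifest
    ),
    class = "marshwave_results"
  )
}

#' @export
print.marshwave_results <- function(x, ...) {
  cat("marshwave pipeline results\n")
  cat(sprintf(
    "  %d tracks over %d sites; %d stations; target stage %.3f\n",
    x$manifest$n_tracks, length(unique(x$events$site)),
    x$manifest$n_stations, x$target_stage
  ))
  cat("  per-site nest date vs indicators:\n")
  print(as.data.frame(x$fig3), row.names = FALSE)
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Writes the pipeline's canonical outputs as plain files: per-individual
#' events, site timing, onsets and the two comparison tables as CSV, the
#' fitted green-wave model and the manifest as JSON.
#'
#' @param results A `marshwave_results` bundle.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
export_results <- function(results, dir) {
  .assert(inherits(results, "marshwave_results"), "results must come from run_greenwave_pipeline()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(results$events, "events.csv"),
    w(results$site_timing, "site_timing.csv"),
    w(results$onsets, "spring_onsets.csv"),
    w(results$fig3, "nest_vs_indicators.csv"),
    w(results$fig4$grid, "indicator_grid.csv")
  )
  gw <- results$greenwave
  model_json <- file.path(dir, "greenwave_model.json")
  jsonlite::write_json(
    list(
      coefficients = as.list(gw$coefficients),
      robust_se = as.list(greenwave_se(gw, "robust")),
      model_se = as.list(greenwave_se(gw, "model")),
      rho = gw$rho, phi = gw$phi,
      n_obs = gw$n_obs, n_studies = gw$n_studies,
      target_stage = results$target_stage
    ),
    model_json,
    auto_unbox = TRUE, digits = NA
  )
  manifest_json <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, manifest_json, auto_unbox = TRUE, digits = NA)
  invisible(c(files, model_json, manifest_json))
}

#' Average cross-site timing offset from a published-style timing table
#'
#' Takes a five-stage timing table (rows: fall migration departure,
#' winter arrival, spring migration departure, breeding site arrival,
#' nest initiation; columns: mean day of year per site group, reference
#' site first) and returns the average, over all stages and non-reference
#' sites, of the difference between each northern group's mean and the
#' reference (southernmost) mean.
#'
#' @param timing A data frame whose first column names the stage and whose
#'   remaining numeric columns are site-group means with the reference
#'   (southernmost) site first.
#' @return A list: `mean_offset_days` and `per_stage` (tibble of offsets
#'   by stage and site).
#' @export
timing_difference_summary <- function(timing) {
  .assert(ncol(timing) >= 3, "need a stage column and at least two site columns")
  required <- c(
    "fall_migration_departure", "winter_arrival",
    "spring_migration_departure", "breeding_site_arrival",
    "nest_initiation"
  )
  stages <- tolower(gsub("[^a-z_]", "", gsub("[ -]+", "_", timing[[1]])))
  missing <- setdiff(required, stages)
  .assert(length(missing) == 0, paste0(
    "missing stage row(s): ", paste(missing, collapse = ", ")
  ))
  ref <- timing[[2]]
  per_stage <- purrr::map_dfr(names(timing)[-(1:2)], function(colname) {
    tibble::tibble(
      stage = stages,
      site = colname,
      offset_days = timing[[colname]] - ref
    )
  })
  list(
    mean_offset_days = mean(per_stage$offset_days),
    per_stage = per_stage
  )
}
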