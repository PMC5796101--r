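#' Validation metrics between measured and estimated rate series
#'
#' Pairs the two series by nearest time within `time_tolerance` (unmatched
#' points are dropped) and computes `R^2 = 1 - SS_res / SS_tot` of the
#' estimates against the measurements, plus the RMSE in rate units.  If a
#' `condition` column is present in both series, a per-condition breakdown
#' is included.
#'
#' @param measured,estimated tibbles/data.frames with `time` (s) and `rate`
#'   columns (e.g. [drawdown_to_rate()] output and pipeline estimates).
#' @param time_tolerance maximum pairing offset, s (default 90).
#' @return An object of class `validation_report`: `pairs` (tibble `time`,
#'   `measured`, `estimated`), `r_squared`, `rmse`, `n`, and optionally
#'   `by_condition`.
#' @export
validation_metrics <- function(measured, estimated, time_tolerance = 90) {
  stopifnot(all(c("time", "rate") %in% names(measured)),
            all(c("time", "rate") %in% names(estimated)))
  m <- dplyr::arrange(tibble::as_tibble(measured), .data$time)
  e <- dplyr::arrange(tibble::as_tibble(estimated), .data$time)
  idx <- vapply(m$time, function(tt) which.min(abs(e$time - tt)), 0L)
  dtau <- abs(e$time[idx] - m$time)
  keep <- dtau <= time_tolerance
  pairs <- tibble::tibble(time = m$time[keep],
                          measured = m$rate[keep],
                          estimated = e$rate[idx][keep])
  if ("condition" %in% names(m)) pairs$condition <- m$condition[keep]
  if (nrow(pairs) < 2) {
    stop("fewer than 2 time-matched pairs within the tolerance",
         call. = FALSE)
  }
  ss_tot <- sum((pairs$measured - mean(pairs$measured))^2)
  if (ss_tot == 0) {
    stop("measured series is constant: R^2 undefined (SS_tot = 0)",
         call. = FALSE)
  }
  ss_res <- sum((pairs$estimated - pairs$measured)^2)
  rep <- list(pairs = pairs,
              r_squared = 1 - ss_res / ss_tot,
              rmse = sqrt(mean((pairs$estimated - pairs$measured)^2)),
              n = nrow(pairs))
  if ("condition" %in% names(pairs)) {
    rep$by_condition <- pairs |>
      dplyr::summarise(
        n = dplyr::n(),
        rmse = sqrt(mean((.data$estimated - .data$measured)^2)),
        r_squared = 1 - sum((.data$estimated - .data$measured)^2) /
          sum((.data$measured - mean(.data$measured))^2),
        .by = "condition")
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n = ", x$n, ", R^2 = ",
      sprintf("%.3f", x$r_squared), ", RMSE = ", sprintf("%.3f", x$rmse),
      " umolCO2 m^-2 s^-1\n", sep = "")
  invisible(x)
}

#' Bell-shaped diurnal global-PPFD profile
#'
#' A clear-sky-like half-sine between sunrise and sunset, zero outside; a
#' simple stand-in for a measured global-horizontal PPFD series.
#'
#' @param hours numeric vector of local decimal hours.
#' @param peak_ppfd maximum horizontal PPFD at mid-day.
#' @param sunrise,sunset local decimal hours.
#' @return A tibble with `hour` and `ghi_ppfd`.
#' @export
ghi_diurnal_profile <- function(hours, peak_ppfd = 1500,
                                sunrise = 5.5, sunset = 19.5) {
  stopifnot(peak_ppfd >= 0, sunset > sunrise)
  frac <- (hours - sunrise) / (sunset - sunrise)
  ghi <- ifelse(frac > 0 & frac < 1, peak_ppfd * sin(pi * frac), 0)
  tibble::tibble(hour = hours, ghi_ppfd = ghi)
}

#' Artificial-light experiment: lamp-lit canopy and its CO2 response
#'
#' The full artificial-light workflow: build the plant and chamber scene,
#' calibrate the overhead lamp so the top sensor reads `target_top_ppfd`,
#' trace the (time-constant) light field once, and evaluate the whole-plant
#' CO2 response on `co2_grid` through the model's light/CO2 separability.
#' Optionally forward-simulates the chamber drawdown the experiment would
#' record.
#'
#' @param plant a [build_plant()] result (default: `build_plant(
#'   plant_config(target_total_leaf_area = 4194.84))`).
#' @param target_top_ppfd calibration target at the top sensor,
#'   umol m^-2 s^-1 (default 833.1).
#' @param co2_grid CO2 mole fractions for the response curve.
#' @param model a [photo_model()].
#' @param materials scene materials (default [default_materials()]; the
#'   chamber is black-clothed, so walls and floor absorb).
#' @param lamp_height_above_canopy lamp mounting height above the canopy
#'   top, m (default 1.5).
#' @param chamber a [chamber_spec()] for the optional drawdown simulation.
#' @param simulate_chamber also forward-simulate the 12 h drawdown from
#'   `c0`?
#' @param c0 initial chamber CO2 for the simulation, umol mol^-1.
#' @param n_rays,seed,... passed to [trace_scene()].
#' @return A list of class `artificial_light_experiment`: `scene`, `map`,
#'   `sensors` (top/middle/bottom readings), `ppfd_table`, `response`
#'   (a `co2_response` tibble), `lamp_flux`, and if requested `trace`
#'   (simulated drawdown) + `rates` (its re-analysis).
#' @export
run_artificial_light_experiment <- function(
    plant = NULL, target_top_ppfd = 833.1,
    co2_grid = seq(200, 1000, by = 50),
    model = photo_model(), materials = default_materials(),
    lamp_height_above_canopy = 1.5, chamber = chamber_spec(),
    simulate_chamber = FALSE, c0 = 1000,
    n_rays = 2e5, seed = 1L, ...) {
  if (is.null(plant)) {
    plant <- build_plant(plant_config(target_total_leaf_area = 4194.84))
  }
  scene <- build_scene(plant)
  z_top <- scene$sensor_heights[["top"]]
  illum <- lamp_illumination(center = c(0, 0, z_top + lamp_height_above_canopy),
                             total_flux = 1000)
  cal <- calibrate_lamp(scene$mesh, materials, illum, target_top_ppfd,
                        n_rays = n_rays, seed = seed, ...)
  map <- trace_scene(scene$mesh, materials, cal$illumination,
                     n_rays = n_rays, seed = seed, ...)
  ppfd_table <- leaf_ppfd_table(map, scene$leaves)
  response <- co2_response(ppfd_table, scene$leaves, co2_grid, model)
  out <- list(scene = scene, map = map,
              sensors = sensor_readings(map),
              ppfd_table = ppfd_table,
              response = response,
              lamp_flux = cal$total_flux)
  if (simulate_chamber) {
    joined <- dplyr::inner_join(ppfd_table,
                                dplyr::select(scene$leaves, "leaf_id",
                                              area_cm2 = "allometric_area"),
                                by = "leaf_id")
    area_m2 <- joined$area_cm2 / 1e4
    s <- model$p_max * sum(area_m2 * (1 - exp(-model$k_light * joined$ppfd)))
    a_tot <- sum(area_m2)
    flux_fun <- function(co2, time) {
      s * (1 - exp(-model$k_co2 * co2)) - model$r_dark * a_tot
    }
    out$trace <- simulate_drawdown(flux_fun, chamber, c0 = c0,
                                   duration = 43200, dt = 5)
    out$rates <- drawdown_to_rate(out$trace, chamber, a_tot)
  }
  class(out) <- "artificial_light_experiment"
  out
}

#' Diurnal natural-light experiment
#'
#' Traces the canopy once per schedule point under the sun position and
#' global PPFD of that moment and assembles the whole-plant rate course.
#' Hours with the sun below the horizon (or zero PPFD) need no trace: every
#' leaf is dark and the rate is the model's dark value.
#'
#' @param plant a [build_plant()] result (same default as
#'   [run_artificial_light_experiment()]).
#' @param latitude,longitude,date,utc_offset site and day (defaults: Suwon,
#'   Korea, 21 July 2016, UTC+9).
#' @param ghi table with `hour` (local decimal hours — the schedule) and
#'   `ghi_ppfd`, e.g. [ghi_diurnal_profile()] or a measured series.
#' @param co2 chamber CO2 schedule: scalar, or vector matching
#'   `nrow(ghi)`.
#' @param diffuse_fraction direct/diffuse split (default 0.3).
#' @param enclosure_transmittance greenhouse glazing transmittance applied
#'   to both components (default 0.7).
#' @param model a [photo_model()].
#' @param materials scene materials; natural-light default keeps the black
#'   chamber walls out of the mesh (`walls = FALSE` in the scene).
#' @param n_rays,seed,... passed to [trace_scene()].
#' @return A tibble of class `diurnal_rates`: `hour`, `zenith`, `ghi_ppfd`,
#'   `co2`, `rate` (umolCO2 m^-2(leaf) s^-1), `total_flux`.
#' @export
run_diurnal_experiment <- function(
    plant = NULL, latitude = 37.45, longitude = 126.98,
    date = "2016-07-21", utc_offset = 9,
    ghi = ghi_diurnal_profile(6:18),
    co2 = 1000, diffuse_fraction = 0.3, enclosure_transmittance = 0.7,
    model = photo_model(), materials = default_materials(),
    n_rays = 1e5, seed = 1L, ...) {
  if (is.null(plant)) {
    plant <- build_plant(plant_config(target_total_leaf_area = 4194.84))
  }
  stopifnot(all(c("hour", "ghi_ppfd") %in% names(ghi)))
  scene <- build_scene(plant, walls = FALSE)
  co2 <- rep_len(co2, nrow(ghi))
  rows <- vector("list", nrow(ghi))
  for (i in seq_len(nrow(ghi))) {
    hr <- ghi$hour[i]
    hh <- floor(hr)
    mm <- round((hr - hh) * 60)
    st <- site_time(latitude, longitude,
                    sprintf("%s %02d:%02d:00", date, hh, mm), utc_offset)
    sp <- solar_position(st)
    dark <- sp$zenith >= 90 || ghi$ghi_ppfd[i] <= 0
    if (dark) {
      rate <- leaf_net_photosynthesis(0, co2[i], model)
      flux <- rate * sum(plant$leaves$allometric_area) / 1e4
    } else {
      illum <- natural_illumination(
        ghi$ghi_ppfd[i], diffuse_fraction,
        zenith = sp$zenith, azimuth = sp$azimuth,
        enclosure_transmittance = enclosure_transmittance)
      map <- trace_scene(scene$mesh, materials, illum,
                         n_rays = n_rays, seed = seed + i, ...)
      tab <- leaf_ppfd_table(map, scene$leaves)
      wpr <- whole_plant_rate(tab, scene$leaves, co2[i], model)
      rate <- wpr$rate_per_leaf_area
      flux <- wpr$total_flux
    }
    rows[[i]] <- tibble::tibble(hour = hr, zenith = sp$zenith,
                                ghi_ppfd = ghi$ghi_ppfd[i], co2 = co2[i],
                                rate = rate, total_flux = flux)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("diurnal_rates", class(out))
  out
}

# ------------------------------------------------------------- config I/O

#' Read / write a pipeline configuration (YAML)
#'
#' A flat-structured YAML file mirroring the construction arguments of the
#' pipeline: `plant` ([plant_config()] fields), `illumination`, `optics`
#' (per-kind `reflectance` / `transmittance`), `trace` (`n_rays`,
#' `max_impacts`, `detector_pitch`, `seed`), `model` ([photo_model()]
#' fields) and `chamber` ([chamber_spec()] fields).  Missing sections fall
#' back to package defaults.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a named list of constructed config
#'   objects (`plant`, `materials`, `model`, `chamber`, `trace`,
#'   `illumination` as raw list).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  out$plant <- do.call(plant_config, raw$plant %||% list())
  if (!is.null(raw$plant$divergence_angles) &&
      is.list(raw$plant$divergence_angles)) {
    # yaml gives named list already; plant_config handled it
  }
  mats <- default_materials()
  for (k in names(raw$optics %||% list())) {
    mats[[k]] <- optical_material(raw$optics[[k]]$reflectance %||% 0,
                                  raw$optics[[k]]$transmittance %||% 0)
  }
  out$materials <- mats
  out$model <- do.call(photo_model, raw$model %||% list())
  ch <- raw$chamber %||% list()
  if (!is.null(ch$dimensions)) ch$dimensions <- as.numeric(ch$dimensions)
  out$chamber <- do.call(chamber_spec, ch)
  out$trace <- utils::modifyList(
    list(n_rays = 1e6, max_impacts = 10, detector_pitch = 0.005, seed = 1L),
    raw$trace %||% list())
  out$illumination <- raw$illumination %||% list()
  out
}

#' @param config a list as produced by [read_pipeline_config()] (or a raw
#'   nested list of the same shape).
#' @rdname read_pipeline_config
#' @return `write_pipeline_config()`: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- list()
  if (!is.null(config$plant)) {
    ser$plant <- unclass(config$plant)
    ser$plant <- Filter(Negate(is.null), ser$plant)
  }
  if (!is.null(config$materials)) {
    ser$optics <- lapply(config$materials, unclass)
  }
  if (!is.null(config$model)) ser$model <- unclass(config$model)
  if (!is.null(config$chamber)) {
    ch <- unclass(config$chamber)
    ch$volume <- NULL
    ser$chamber <- ch
  }
  if (!is.null(config$trace)) ser$trace <- config$trace
  if (!is.null(config$illumination)) ser$illumination <- config$illumination
  yaml::write_yaml(ser, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
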