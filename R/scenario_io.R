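#' Read and write barn scenario files
#'
#' A scenario bundles zone, climate, event and herd configuration plus the
#' simulation duration and seed into a single JSON (or YAML) document, so a
#' synthetic experiment is fully described by one text file.
#'
#' @param zones List of [zone_config()] objects.
#' @param climate A [climate_config()].
#' @param events An [event_schedule()].
#' @param herd Optional [herd_config()] (needed for emission studies).
#' @param duration_days Simulation length in days.
#' @param seed Integer seed.
#' @return `barn_scenario()` returns an object of class `barn_scenario`;
#'   `read_scenario()` reconstructs one from file.
#' @export
barn_scenario <- function(zones, climate = climate_config(),
                          events = event_schedule(), herd = NULL,
                          duration_days = 1, seed = 1) {
  if (inherits(zones, "zone_config")) zones <- list(zones)
  structure(list(zones = zones, climate = climate, events = events,
                 herd = herd, duration_days = duration_days, seed = seed),
            class = "barn_scenario")
}

#' @rdname barn_scenario
#' @param scenario A `barn_scenario`.
#' @param path File path; extension selects the format (`.json`, `.yaml`/`.yml`).
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass_deep(scenario)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_barnsense("the 'yaml' package is required for YAML scenarios",
                     "barnsense_config_error")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname barn_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_barnsense("the 'yaml' package is required for YAML scenarios",
                     "barnsense_config_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  zones <- lapply(x$zones, function(z)
    zone_config(z$zone_id, z$volume, unlist(z$ventilation_rate),
                z$nh3_source %||% 0, z$co2_source %||% 0, z$h2s_source %||% 0))
  cl <- x$climate
  climate <- do.call(climate_config, cl[names(cl) %in%
                                          names(formals(climate_config))])
  ev <- x$events
  events <- event_schedule(unlist(ev$event_times) %||% character(0),
                           ev$multiplier %||% 2, ev$duration_min %||% 60)
  herd <- if (!is.null(x$herd))
    herd_config(x$herd$n_animals, x$herd$body_mass, x$herd$milk_yield,
                x$herd$pregnancy_days %||% 0)
  barn_scenario(zones, climate, events, herd,
                x$duration_days %||% 1, x$seed %||% 1)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write ground truth to per-zone CSV files with a JSON parameter sidecar
#'
#' One CSV per zone (and one for the outdoor point) with an ISO-8601
#' timestamp column and one column per channel; units are recorded in a
#' leading comment line. The complete generating parameter set, including the
#' seed, is written alongside as `ground_truth_params.json`.
#'
#' @param truth A [make_truth()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_truth_csv <- function(truth, dir) {
  if (!inherits(truth, "barn_truth"))
    stop_barnsense("truth must be a barn_truth", "barnsense_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units_line <- paste0(
    "# units: temp degC; rh %; sound dBA; lux lx; h2s,nh3 ppm; co2 ppm; ",
    "voc,nox ppb; pm* ug m-3; *_gm3 g m-3")
  paths <- character(0)
  all_series <- c(truth$zones, list(outdoor = truth$outdoor))
  for (nm in names(all_series)) {
    df <- all_series[[nm]]
    out <- cbind(timestamp = format_iso8601(as.numeric(truth$start) + df$time),
                 df[, setdiff(names(df), "time")])
    p <- file.path(dir, paste0("truth_", nm, ".csv"))
    con <- file(p, "w")
    writeLines(units_line, con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, "ground_truth_params.json")
  jsonlite::write_json(
    c(unclass_deep(truth$params),
      list(seed = truth$seed, dt = truth$dt,
           start = format_iso8601(as.numeric(truth$start)))),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, sidecar))
}
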