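#' Herd configuration for metabolic CO2 production
#'
#' Describes the lactating herd whose metabolic CO2 output drives the
#' tracer-gas balance.
#'
#' @param n_animals Number of animals housed (> 0).
#' @param body_mass Mean body mass, kg per head (> 0; default 650 kg for a
#'   lactating dairy cow).
#' @param milk_yield Milk production, kg head^-1 day^-1 (> 0).
#' @param pregnancy_days Days of pregnancy (>= 0; 0 if not modelled).
#' @return An object of class `herd_config`.
#' @export
herd_config <- function(n_animals, body_mass = 650, milk_yield,
                        pregnancy_days = 0) {
  if (n_animals <= 0 || body_mass <= 0 || milk_yield <= 0)
    stop_barnsense("n_animals, body_mass and milk_yield must be positive",
                   "barnsense_config_error")
  if (pregnancy_days < 0)
    stop_barnsense("pregnancy_days must be >= 0", "barnsense_config_error")
  structure(list(n_animals = n_animals, body_mass = body_mass,
                 milk_yield = milk_yield, pregnancy_days = pregnancy_days),
            class = "herd_config")
}

#' Herd metabolic CO2 production with temperature correction
#'
#' CIGR/VERA-style heat-production model for lactating dairy cows. Per head,
#' total heat production at 20 degC is
#' `Phi_tot = 5.6 m^0.75 + 22 Y + 1.6e-5 p^3` (W), with body mass `m` (kg),
#' milk yield `Y` (kg/day) and pregnancy days `p`. Ambient-temperature
#' correction: `Phi(T) = Phi_tot (1000 + 4 (20 - T)) / 1000`. One
#' heat-producing unit (hpu) is 1000 W, and a herd exhales 0.185 m^3 h^-1 of
#' CO2 per hpu; volume is converted to mass at the barn temperature and
#' pressure via the ideal-gas CO2 density.
#'
#' @param herd A [herd_config()].
#' @param temp Barn air temperature, degC (vectorized). A warning is issued
#'   outside -25..45 degC, where the linear correction is extrapolated.
#' @param pressure Barometric pressure, Pa.
#' @return Total herd CO2 production, g h^-1 (per `temp` value).
#' @examples
#' herd <- herd_config(140, body_mass = 650, milk_yield = 37)
#' co2_production(herd, temp = 20) / 140   # ~519.6 g/h per head
#' @export
co2_production <- function(herd, temp, pressure = 101325) {
  if (!inherits(herd, "herd_config"))
    stop_barnsense("herd must be a herd_config", "barnsense_config_error")
  if (any(temp < -25 | temp > 45, na.rm = TRUE))
    warning("temperature outside [-25, 45] degC: correction extrapolated",
            call. = FALSE)
  phi_tot <- 5.6 * herd$body_mass^0.75 + 22 * herd$milk_yield +
    1.6e-5 * herd$pregnancy_days^3
  hpu <- phi_tot * (1000 + 4 * (20 - temp)) / 1000 / 1000
  vol <- 0.185 * hpu                                    # m^3 h^-1 per head
  co2_density <- ppm_to_mass_conc(1e6, "co2", temp = temp, pressure = pressure)
  vol * co2_density * herd$n_animals
}

#' Ammonia emission from the CO2 tracer-gas balance
#'
#' The tracer balance assumes NH3 and CO2 are removed by the same
#' ventilation air flow, so the unknown ventilation rate cancels:
#' `E_NH3 = P_CO2 * (C_NH3_barn - C_NH3_outside) /
#'          (C_CO2_barn - C_CO2_outside)`
#' with concentrations in g m^-3 and `P_CO2` (herd CO2 production) in
#' g h^-1.
#'
#' @param p_co2 Herd CO2 production, g h^-1.
#' @param c_nh3_barn,c_nh3_outside Indoor and background NH3, g m^-3.
#' @param c_co2_barn,c_co2_outside Indoor and background CO2, g m^-3.
#' @param on_invalid What to do when the CO2 difference is non-positive
#'   (the estimate is then undefined): `"error"` (default) or `"na"` (flag
#'   the hour and return `NA`, as in hourly pipelines).
#' @return NH3 emission, g h^-1 (vectorized).
#' @examples
#' nh3_emission(50000, 5e-4, 0, 0.5, 0)   # 50 g/h
#' @export
nh3_emission <- function(p_co2, c_nh3_barn, c_nh3_outside,
                         c_co2_barn, c_co2_outside,
                         on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  d_co2 <- c_co2_barn - c_co2_outside
  bad <- !is.na(d_co2) & d_co2 <= 0
  if (any(bad)) {
    if (on_invalid == "error")
      stop_barnsense("non-positive CO2 difference: emission estimate undefined",
                     "barnsense_undefined_estimate")
    d_co2[bad] <- NA_real_
  }
  p_co2 * (c_nh3_barn - c_nh3_outside) / d_co2
}

#' Daily emission summary
#'
#' Averages hourly emission estimates over a day and expresses the result
#' per animal: `E_daily = 24 * mean(valid hourly E) / n_animals`
#' (g animal^-1 day^-1). A day with fewer than `min_valid_hours` valid hours
#' is marked missing.
#'
#' @param hourly Numeric vector of hourly NH3 emissions for one day,
#'   g h^-1; invalid hours as `NA`.
#' @param herd A [herd_config()].
#' @param min_valid_hours Minimum number of valid hours (default 12).
#' @return List with `E_g_per_h` (daily mean), `E_g_per_animal_day`,
#'   `valid_hours` and `missing`.
#' @export
daily_emission <- function(hourly, herd, min_valid_hours = 12) {
  valid <- sum(!is.na(hourly))
  if (valid < min_valid_hours)
    return(list(E_g_per_h = NA_real_, E_g_per_animal_day = NA_real_,
                valid_hours = valid, missing = TRUE))
  m <- mean(hourly, na.rm = TRUE)
  list(E_g_per_h = m, E_g_per_animal_day = 24 * m / herd$n_animals,
       valid_hours = valid, missing = FALSE)
}

#' Estimate barn NH3 emissions from indoor and outdoor device series
#'
#' Full tracer-gas pipeline on an hourly basis: indoor NH3, CO2 and
#' temperature are averaged across the barn devices hour by hour; indoor and
#' outdoor mixing ratios are converted to mass concentrations at their
#' respective measured temperatures; herd CO2 production is evaluated at the
#' hourly indoor temperature (capturing the fluctuating temperature over the
#' day); hourly emissions from the tracer balance are then averaged into
#' daily and per-animal values. Hours with a non-positive indoor-outdoor CO2
#' difference are flagged invalid and excluded from the daily mean.
#'
#' @param indoor A `device_series` at hourly resolution containing channels
#'   `nh3`, `co2` and `temp` for one or more barn nodes (several `node_id`s
#'   are averaged), or a list of such series.
#' @param outdoor Hourly `device_series` of the background node (channels
#'   `nh3`, `co2`, `temp`).
#' @param herd A [herd_config()].
#' @param pressure Barometric pressure, Pa.
#' @param min_valid_hours Passed to [daily_emission()].
#' @return An object of class `emission_estimate`: list with `hourly`
#'   (`timestamp, p_co2, c_nh3_barn, c_nh3_out, c_co2_barn, c_co2_out,
#'   E_g_per_h, valid`) and `daily`
#'   (`day, E_g_per_h, E_g_per_animal_day, valid_hours`).
#' @export
estimate_emissions <- function(indoor, outdoor, herd, pressure = 101325,
                               min_valid_hours = 12) {
  if (is.list(indoor) && !is.data.frame(indoor))
    indoor <- do.call(rbind, lapply(indoor, as.data.frame))
  need <- c("nh3", "co2", "temp")
  for (ch in need) {
    if (!ch %in% indoor$channel || !ch %in% outdoor$channel)
      stop_barnsense(sprintf("channel '%s' required indoors and outdoors", ch),
                     "barnsense_config_error")
  }
  mean_by_hour <- function(s, ch) {
    x <- s[s$channel == ch & !is.na(s$value), ]
    tapply(x$value, x$timestamp, mean)
  }
  in_nh3 <- mean_by_hour(indoor, "nh3")
  in_co2 <- mean_by_hour(indoor, "co2")
  in_temp <- mean_by_hour(indoor, "temp")
  out_nh3 <- mean_by_hour(outdoor, "nh3")
  out_co2 <- mean_by_hour(outdoor, "co2")
  out_temp <- mean_by_hour(outdoor, "temp")
  hours <- Reduce(intersect, list(names(in_nh3), names(in_co2), names(in_temp),
                                  names(out_nh3), names(out_co2),
                                  names(out_temp)))
  if (!length(hours))
    stop_barnsense("no common hours between indoor and outdoor series",
                   "barnsense_config_error")
  hours <- hours[order(as.numeric(hours))]
  ts <- as.numeric(hours)
  ti <- in_temp[hours]; to <- out_temp[hours]
  hh <- data.frame(
    timestamp = ts,
    p_co2 = co2_production(herd, temp = ti, pressure = pressure),
    c_nh3_barn = ppm_to_mass_conc(in_nh3[hours], "nh3", ti, pressure),
    c_nh3_out = ppm_to_mass_conc(out_nh3[hours], "nh3", to, pressure),
    c_co2_barn = ppm_to_mass_conc(in_co2[hours], "co2", ti, pressure),
    c_co2_out = ppm_to_mass_conc(out_co2[hours], "co2", to, pressure),
    row.names = NULL)
  hh$E_g_per_h <- nh3_emission(hh$p_co2, hh$c_nh3_barn, hh$c_nh3_out,
                               hh$c_co2_barn, hh$c_co2_out, on_invalid = "na")
  hh$valid <- !is.na(hh$E_g_per_h)
  day <- floor(hh$timestamp / 86400)
  daily <- do.call(rbind, lapply(split(seq_len(nrow(hh)), day), function(idx) {
    d <- daily_emission(hh$E_g_per_h[idx], herd, min_valid_hours)
    data.frame(day = day[idx[1]], E_g_per_h = d$E_g_per_h,
               E_g_per_animal_day = d$E_g_per_animal_day,
               valid_hours = d$valid_hours, row.names = NULL)
  }))
  structure(list(hourly = hh, daily = daily, herd = herd,
                 pressure = pressure),
            class = "emission_estimate")
}

#' @export
print.emission_estimate <- function(x, ...) {
  cat(sprintf("NH3 emission estimate (CO2 tracer), %d hour(s), %d day(s)\n",
              nrow(x$hourly), nrow(x$daily)))
  ok <- !is.na(x$daily$E_g_per_animal_day)
  if (any(ok))
    cat(sprintf("  per-animal daily emission: %.1f g animal-1 day-1 (mean over %d day(s))\n",
                mean(x$daily$E_g_per_animal_day[ok]), sum(ok)))
  cat(sprintf("  invalid hours (non-positive CO2 difference): %d\n",
              sum(!x$hourly$valid)))
  invisible(x)
}

#' Write hourly and daily emission CSV files
#'
#' @param estimate An [estimate_emissions()] result.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_emission_csv <- function(estimate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- file.path(dir, "emission_hourly.csv")
  pd <- file.path(dir, "emission_daily.csv")
  utils::write.csv(estimate$hourly, ph, row.names = FALSE)
  utils::write.csv(estimate$daily, pd, row.names = FALSE)
  invisible(c(ph, pd))
}
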