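#' Zone configuration for the synthetic barn
#'
#' Describes one well-mixed compartment of a livestock building: its volume,
#' ventilation rate and constant gas source strengths. Gas concentrations in
#' the zone follow the single-compartment mass balance
#' `V dC/dt = S(t) + Q(t) (C_out - C)`.
#'
#' @param zone_id Character identifier, unique within a scenario.
#' @param volume Zone air volume in m^3 (> 0).
#' @param ventilation_rate Ventilation rate in m^3 h^-1; a scalar, or a
#'   numeric vector with one value per 10 s simulation step (> 0 everywhere).
#' @param nh3_source,co2_source,h2s_source Gas emission source strengths in
#'   g h^-1 (>= 0). Feeding events scale these via the event schedule.
#'
#' @return An object of class `zone_config`.
#' @seealso [make_truth()], [steady_state_conc()]
#' @export
zone_config <- function(zone_id, volume, ventilation_rate,
                        nh3_source = 0, co2_source = 0, h2s_source = 0) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop_barnsense("zone volume must be a positive scalar (m^3)",
                   "barnsense_config_error")
  if (!is.numeric(ventilation_rate) || any(ventilation_rate <= 0))
    stop_barnsense("ventilation_rate must be positive at all times (m^3 h^-1)",
                   "barnsense_config_error")
  src <- c(nh3 = nh3_source, co2 = co2_source, h2s = h2s_source)
  if (any(src < 0))
    stop_barnsense("gas sources must be >= 0 (g h^-1)", "barnsense_config_error")
  structure(list(zone_id = as.character(zone_id), volume = volume,
                 ventilation_rate = ventilation_rate,
                 nh3_source = nh3_source, co2_source = co2_source,
                 h2s_source = h2s_source),
            class = "zone_config")
}

#' Climate configuration for the synthetic barn
#'
#' Outdoor climate and ambient (non gas-balance) channel levels. Outdoor
#' temperature is a sinusoid; indoor temperature is the outdoor sinusoid plus
#' a constant animal-heat offset (default 3 degC, the typical indoor excess in
#' an open dairy barn).
#'
#' @param mean_temp Daily mean outdoor temperature, degC.
#' @param diurnal_amplitude Half-range of the outdoor temperature sinusoid,
#'   degC (>= 0). Set 0 for a steady scenario.
#' @param peak_hour Hour of day at which temperature peaks, in `[0, 24)`.
#' @param mean_rh Mean relative humidity, percent, in `[0, 100]`.
#' @param outdoor_nh3,outdoor_h2s Outdoor background mixing ratios, ppm (>= 0).
#' @param outdoor_co2 Outdoor background CO2, ppm (>= 400, the NDIR sensor
#'   range floor).
#' @param animal_heat_offset Constant indoor minus outdoor temperature, degC.
#' @param pressure Barometric pressure, Pa.
#' @param rh_ar1_phi,rh_noise_sd AR(1) coefficient and innovation SD (percent
#'   RH) of the humidity fluctuation around `mean_rh`.
#' @param sound_mean Mean sound pressure level, dBA.
#' @param lux_peak Midday peak illuminance, lux (daylight half-sinusoid
#'   between 06:00 and 18:00; 0 at night).
#' @param pm25_mean Mean PM2.5, ug m^-3; other PM fractions are scaled from it.
#' @param voc_mean,nox_mean Mean VOC (ppb) and NOx (ppb) index levels.
#'
#' @return An object of class `climate_config`.
#' @export
climate_config <- function(mean_temp = 15, diurnal_amplitude = 5,
                           peak_hour = 14, mean_rh = 65,
                           outdoor_nh3 = 0.1, outdoor_co2 = 420,
                           outdoor_h2s = 0, animal_heat_offset = 3,
                           pressure = 101325,
                           rh_ar1_phi = 0.9, rh_noise_sd = 2,
                           sound_mean = 60, lux_peak = 5000,
                           pm25_mean = 15, voc_mean = 800, nox_mean = 100) {
  if (mean_rh < 0 || mean_rh > 100)
    stop_barnsense("mean_rh must lie in [0, 100]", "barnsense_config_error")
  if (outdoor_co2 < 400)
    stop_barnsense("outdoor_co2 must be >= 400 ppm (sensor range floor)",
                   "barnsense_config_error")
  if (outdoor_nh3 < 0 || outdoor_h2s < 0)
    stop_barnsense("outdoor backgrounds must be >= 0", "barnsense_config_error")
  if (diurnal_amplitude < 0)
    stop_barnsense("diurnal_amplitude must be >= 0", "barnsense_config_error")
  if (peak_hour < 0 || peak_hour >= 24)
    stop_barnsense("peak_hour must lie in [0, 24)", "barnsense_config_error")
  structure(as.list(environment()), class = "climate_config")
}

#' Feeding-event schedule
#'
#' Scheduled management events (feed delivery) multiply all zone gas sources
#' for a fixed duration, reproducing the concentration peaks seen around
#' feeding times. Defaults: feeds at 07:15 and 16:30, doubling sources for
#' 60 minutes.
#'
#' @param event_times Character vector of `"HH:MM"` times of day.
#' @param multiplier Source multiplier during an event (>= 1).
#' @param duration_min Event duration in minutes (> 0).
#'
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(event_times = c("07:15", "16:30"),
                           multiplier = 2, duration_min = 60) {
  hours <- if (length(event_times)) parse_hhmm(event_times) else numeric(0)
  if (multiplier < 1)
    stop_barnsense("event multiplier must be >= 1", "barnsense_config_error")
  if (duration_min <= 0)
    stop_barnsense("event duration must be positive", "barnsense_config_error")
  structure(list(event_times = event_times, event_hours = hours,
                 multiplier = multiplier, duration_min = duration_min),
            class = "event_schedule")
}

#' Steady-state concentration of a well-mixed zone
#'
#' Closed-form steady state of the single-compartment mass balance:
#' `C = background + source / ventilation`.
#'
#' @param source Gas source strength, g h^-1.
#' @param ventilation Ventilation rate, m^3 h^-1 (> 0).
#' @param background Background (inlet air) concentration, g m^-3.
#' @return Steady-state concentration, g m^-3.
#' @examples
#' steady_state_conc(50, 10000, 0)  # 0.005 g m^-3 = 5 mg m^-3
#' @export
steady_state_conc <- function(source, ventilation, background = 0) {
  if (any(ventilation <= 0))
    stop_barnsense("ventilation must be > 0", "barnsense_domain_error")
  background + source / ventilation
}

#' Generate ground-truth environmental fields for a synthetic barn
#'
#' Produces per-zone time series at 10 s resolution for every sensor channel,
#' plus an outdoor background point, with the full generating parameter set
#' recorded so downstream estimators can be validated by parameter recovery.
#'
#' Gas concentrations follow the well-mixed mass balance
#' `V dC/dt = S(t) + Q(t) (C_out - C)` integrated with the exact exponential
#' update for piecewise-constant coefficients on each 10 s step:
#' `C[k+1] = Css_k + (C[k] - Css_k) exp(-Q_k dt / V)` with
#' `Css_k = C_out_k + S_k / Q_k`. The state is carried in g m^-3; the
#' sensor-facing ppm channels are converted at the zone's instantaneous
#' temperature and the scenario pressure.
#'
#' @param zones A `zone_config` or list of them.
#' @param climate A [climate_config()].
#' @param events An [event_schedule()]; use
#'   `event_schedule(character(0))` for none.
#' @param duration_days Length of the simulation in days (>= 1).
#' @param seed Integer seed; identical `(configuration, seed)` pairs yield
#'   bit-identical output.
#' @param init `"background"` starts gas concentrations at the outdoor
#'   background (a ventilation transient follows); `"steady"` starts at the
#'   initial steady state, which is exact for constant coefficients.
#' @param start POSIXct start of the simulated period (UTC midnight
#'   recommended so hour-of-day arithmetic is transparent).
#'
#' @return An object of class `barn_truth`: a list with `zones` (named list
#'   of data frames, one row per 10 s step, columns `time` in seconds since
#'   `start`, every sensor channel in engineering units, and the gas state in
#'   g m^-3 as `nh3_gm3`, `co2_gm3`, `h2s_gm3`), `outdoor` (same layout),
#'   `params`, `seed`, `dt` and `start`.
#' @export
make_truth <- function(zones, climate = climate_config(),
                       events = event_schedule(), duration_days = 1,
                       seed = 1, init = c("background", "steady"),
                       start = as.POSIXct("2023-06-01", tz = "UTC")) {
  init <- match.arg(init)
  if (inherits(zones, "zone_config")) zones <- list(zones)
  if (!length(zones) || !all(vapply(zones, inherits, logical(1), "zone_config")))
    stop_barnsense("zones must be zone_config objects", "barnsense_config_error")
  if (!inherits(climate, "climate_config"))
    stop_barnsense("climate must be a climate_config", "barnsense_config_error")
  if (duration_days < 1)
    stop_barnsense("duration_days must be >= 1", "barnsense_config_error")
  ids <- vapply(zones, `[[`, character(1), "zone_id")
  if (anyDuplicated(ids))
    stop_barnsense("zone ids must be unique", "barnsense_config_error")

  dt <- 10                                  # seconds; fastest sensor rate
  n <- as.integer(round(duration_days * 86400 / dt))
  t_sec <- (seq_len(n) - 1) * dt
  hod <- (t_sec / 3600) %% 24

  temp_out <- climate$mean_temp +
    climate$diurnal_amplitude * cos(2 * pi * (hod - climate$peak_hour) / 24)
  temp_in <- temp_out + climate$animal_heat_offset
  mult <- event_multiplier(hod, events)
  lux_day <- climate$lux_peak * pmax(0, sin(pi * (hod - 6) / 12))

  bg_ppm <- c(nh3 = climate$outdoor_nh3, co2 = climate$outdoor_co2,
              h2s = climate$outdoor_h2s)

  truth <- with_seed(seed, {
    out <- list(zones = list())
    for (z in zones) {
      q <- if (length(z$ventilation_rate) == 1L)
        rep(z$ventilation_rate, n) else z$ventilation_rate
      if (length(q) != n)
        stop_barnsense("time-varying ventilation must have one value per step",
                       "barnsense_config_error")
      df <- data.frame(time = t_sec, temp = temp_in,
                       rh = ar1_clipped(n, climate$mean_rh, climate$rh_ar1_phi,
                                        climate$rh_noise_sd, 0, 100))
      for (g in GAS_CHANNELS) {
        c_out <- ppm_to_mass_conc(bg_ppm[[g]], g, temp = temp_out,
                                  pressure = climate$pressure)
        s <- z[[paste0(g, "_source")]] * mult
        cm <- integrate_mass_balance(z$volume, s, q, c_out, dt, init)
        df[[paste0(g, "_gm3")]] <- cm
        df[[g]] <- mass_conc_to_ppm(cm, g, temp = temp_in,
                                    pressure = climate$pressure)
      }
      df$sound <- climate$sound_mean + stats::rnorm(n, 0, 1.5)
      df$lux <- pmax(0, lux_day + stats::rnorm(n, 0, climate$lux_peak * 0.01))
      pm_scale <- c(pm1 = 0.5, pm25 = 1, pm4 = 1.3, pm10 = 2)
      for (p in names(pm_scale))
        df[[p]] <- ar1_clipped(n, climate$pm25_mean * pm_scale[[p]], 0.9,
                               climate$pm25_mean * 0.05, 0, Inf)
      df$voc <- ar1_clipped(n, climate$voc_mean, 0.9, climate$voc_mean * 0.02,
                            500, 10000)
      df$nox <- ar1_clipped(n, climate$nox_mean, 0.9, climate$nox_mean * 0.02,
                            50, 650)
      out$zones[[z$zone_id]] <- df[, c("time", CHANNELS,
                                       paste0(GAS_CHANNELS, "_gm3"))]
    }
    # Outdoor background monitoring point: gases sit at the background level.
    od <- data.frame(time = t_sec, temp = temp_out,
                     rh = ar1_clipped(n, climate$mean_rh, climate$rh_ar1_phi,
                                      climate$rh_noise_sd, 0, 100))
    for (g in GAS_CHANNELS) {
      od[[paste0(g, "_gm3")]] <- ppm_to_mass_conc(bg_ppm[[g]], g,
                                                  temp = temp_out,
                                                  pressure = climate$pressure)
      od[[g]] <- rep(bg_ppm[[g]], n)
    }
    od$sound <- climate$sound_mean - 10 + stats::rnorm(n, 0, 1.5)
    od$lux <- pmax(0, lux_day + stats::rnorm(n, 0, climate$lux_peak * 0.01))
    pm_scale <- c(pm1 = 0.25, pm25 = 0.5, pm4 = 0.65, pm10 = 1)
    for (p in names(pm_scale))
      od[[p]] <- ar1_clipped(n, climate$pm25_mean * pm_scale[[p]], 0.9,
                             climate$pm25_mean * 0.025, 0, Inf)
    od$voc <- ar1_clipped(n, 500, 0.9, 5, 500, 10000)
    od$nox <- ar1_clipped(n, climate$nox_mean, 0.9, climate$nox_mean * 0.02,
                          50, 650)
    out$outdoor <- od[, c("time", CHANNELS, paste0(GAS_CHANNELS, "_gm3"))]
    out
  })

  structure(list(zones = truth$zones, outdoor = truth$outdoor,
                 params = list(zones = zones, climate = climate,
                               events = events,
                               duration_days = duration_days, init = init),
                 seed = seed, dt = dt, start = start),
            class = "barn_truth")
}

# Exact exponential update of V dC/dt = S + Q (C_out - C) with
# piecewise-constant S (g/h), Q (m^3/h), C_out (g/m^3) over each step.
integrate_mass_balance <- function(volume, s, q, c_out, dt, init) {
  n <- length(s)
  if (length(q) == 1L) q <- rep(q, n)
  if (length(c_out) == 1L) c_out <- rep(c_out, n)
  css <- c_out + s / q
  a <- exp(-q * (dt / 3600) / volume)
  conc <- numeric(n)
  conc[1L] <- if (init == "steady") css[1L] else c_out[1L]
  if (n > 1L) for (k in seq_len(n - 1L))
    conc[k + 1L] <- css[k] + (conc[k] - css[k]) * a[k]
  conc
}

event_multiplier <- function(hod, events) {
  mult <- rep(1, length(hod))
  if (!inherits(events, "event_schedule"))
    stop_barnsense("events must be an event_schedule", "barnsense_config_error")
  dur_h <- events$duration_min / 60
  for (h0 in events$event_hours) {
    inside <- hod >= h0 & hod < h0 + dur_h
    if (h0 + dur_h > 24)                     # event wrapping past midnight
      inside <- inside | hod < (h0 + dur_h - 24)
    mult[inside] <- events$multiplier
  }
  mult
}

ar1_clipped <- function(n, mean, phi, innov_sd, lo, hi) {
  if (innov_sd <= 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  x <- stats::rnorm(n, 0, innov_sd)
  x <- as.numeric(stats::filter(x, phi, method = "recursive"))
  pmin(hi, pmax(lo, mean + x))
}

#' @export
print.barn_truth <- function(x, ...) {
  cat("Synthetic barn ground truth\n")
  cat(sprintf("  zones: %s (+ outdoor background)\n",
              paste(names(x$zones), collapse = ", ")))
  cat(sprintf("  duration: %g day(s) at %g s resolution (%d steps)\n",
              x$params$duration_days, x$dt, nrow(x$outdoor)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
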