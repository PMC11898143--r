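#' Calibration parameters for a gas sensor channel
#'
#' Holds the offset/gain pair written to the sensor board's EEPROM together
#' with calibration metadata. Electrochemical channels (NH3, H2S) use a
#' two-point span calibration (offset and gain); the NDIR CO2 channel uses a
#' zero (offset-only) calibration against a reference analyzer.
#'
#' @param channel Channel name (`"nh3"`, `"h2s"`, `"co2"`, ...).
#' @param offset Offset in raw-signal units (nA for electrochemical, ppm for
#'   CO2).
#' @param gain Gain in raw-signal units per ppm; `NA` for zero-calibrated
#'   channels, strictly positive otherwise.
#' @param method `"span"` or `"zero"`.
#' @param calibrated_at Timestamp of the calibration.
#' @param reference_concentrations The known concentrations used, ppm.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(channel, offset, gain = NA_real_,
                               method = c("span", "zero"),
                               calibrated_at = Sys.time(),
                               reference_concentrations = NULL) {
  method <- match.arg(method)
  if (method == "span" && (is.na(gain) || gain <= 0))
    stop_barnsense("span calibration requires a positive gain",
                   "barnsense_sensor_fault")
  structure(list(channel = channel, offset = offset, gain = gain,
                 method = method, calibrated_at = calibrated_at,
                 reference_concentrations = reference_concentrations),
            class = "calibration_params")
}

#' Two-point span calibration of an electrochemical sensor
#'
#' Fits the linear response `signal = offset + gain * concentration` through
#' two measurements at known concentrations, as done on the calibration bench
#' with a dynamic dilution calibrator. Applying [apply_calibration()] to the
#' two calibration signals returns the two known concentrations exactly.
#'
#' @param conc Numeric length-2: the two known concentrations, ppm (distinct).
#' @param signal Numeric length-2: the raw sensor signals at those
#'   concentrations (nA).
#' @param channel Channel being calibrated (default `"nh3"`).
#' @return A [calibration_params()] with
#'   `gain = (signal2 - signal1) / (conc2 - conc1)` and
#'   `offset = signal1 - gain * conc1`.
#' @examples
#' span_calibrate(c(0, 50), c(40, 5040))  # gain 100 nA/ppm, offset 40 nA
#' @export
span_calibrate <- function(conc, signal, channel = "nh3") {
  if (length(conc) != 2L || length(signal) != 2L)
    stop_barnsense("span calibration needs exactly two points",
                   "barnsense_config_error")
  if (conc[1] == conc[2])
    stop_barnsense("the two calibration concentrations must differ",
                   "barnsense_degenerate_calibration")
  gain <- (signal[2] - signal[1]) / (conc[2] - conc[1])
  if (gain <= 0)
    stop_barnsense("inferred non-positive gain: sensor fault",
                   "barnsense_sensor_fault")
  calibration_params(channel, offset = signal[1] - gain * conc[1], gain = gain,
                     method = "span", reference_concentrations = conc)
}

#' Zero (offset) calibration of the CO2 channel
#'
#' One-point calibration against a reference analyzer measuring the same
#' air: `offset = raw_reading - reference_ppm`, so the corrected reading at
#' the calibration point equals the reference exactly.
#'
#' @param raw_reading Sensor reading, ppm.
#' @param reference_ppm Reference analyzer reading, ppm; must lie within the
#'   sensor range.
#' @param range Sensor range, ppm (default the NDIR 400-10000 ppm).
#' @return A [calibration_params()] with `method = "zero"`.
#' @examples
#' zero_calibrate(655, 609)  # offset 46 ppm
#' @export
zero_calibrate <- function(raw_reading, reference_ppm, range = c(400, 10000)) {
  if (reference_ppm < range[1] || reference_ppm > range[2])
    stop_barnsense(sprintf("reference %g ppm outside sensor range [%g, %g]",
                           reference_ppm, range[1], range[2]),
                   "barnsense_range_error")
  calibration_params("co2", offset = raw_reading - reference_ppm,
                     method = "zero",
                     reference_concentrations = reference_ppm)
}

#' Apply stored calibration parameters to a raw signal
#'
#' Span-calibrated channels: `ppm = (raw - offset) / gain`. Zero-calibrated
#' channels: `ppm = raw - offset`. Optionally clips the result to the
#' channel's measurement range.
#'
#' @param raw_signal Numeric vector of raw readings.
#' @param params A [calibration_params()].
#' @param range Optional length-2 numeric range to clip to (ppm).
#' @return Concentration in ppm.
#' @examples
#' p <- span_calibrate(c(0, 50), c(40, 5040))
#' apply_calibration(5040, p)  # 50 ppm
#' @export
apply_calibration <- function(raw_signal, params, range = NULL) {
  if (!inherits(params, "calibration_params"))
    stop_barnsense("channel is uncalibrated: no calibration parameters",
                   "barnsense_uncalibrated")
  ppm <- if (params$method == "span")
    (raw_signal - params$offset) / params$gain
  else raw_signal - params$offset
  if (!is.null(range)) ppm <- pmin(range[2], pmax(range[1], ppm))
  ppm
}

#' Simulated electrochemical sensor signal
#'
#' Bench-mode transfer function for calibration studies: a linear raw-current
#' response `offset + gain * ppm` with optional Gaussian noise, in nA.
#' Typical electrochemical sensitivities lie in 10-200 nA/ppm.
#'
#' @param ppm Applied concentration, ppm.
#' @param gain True sensitivity, nA/ppm.
#' @param offset True zero-level offset, nA.
#' @param noise_sd Gaussian noise SD on the signal, nA.
#' @return Raw signal in nA.
#' @export
electrochemical_signal <- function(ppm, gain, offset, noise_sd = 0) {
  offset + gain * ppm + if (noise_sd > 0)
    stats::rnorm(length(ppm), 0, noise_sd) else 0
}

#' Store and load calibration parameters as JSON
#'
#' Emulates the sensor board's small EEPROM with a per-board JSON document.
#'
#' @param params A [calibration_params()].
#' @param path File path.
#' @return `read_calibration()` returns the `calibration_params`.
#' @export
write_calibration <- function(params, path) {
  x <- unclass(params)
  x$calibrated_at <- format(x$calibrated_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(x$channel, x$offset, x$gain %||% NA_real_, x$method,
                     as.POSIXct(x$calibrated_at, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC"),
                     x$reference_concentrations)
}

#' Multi-device repeatability report
#'
#' Quantifies how closely several nodes agree when exposed to the same
#' conditions. At every common measurement interval and channel, each node's
#' absolute error is computed against a reference -- by default the
#' cross-node mean at that interval (appropriate for ambient-air checks with
#' no independent truth), optionally a known applied concentration. The
#' per-interval mean and sample standard deviation of the absolute errors
#' are then averaged over time into a per-channel summary, in absolute units
#' and relative to the interval reference.
#'
#' @param series Data frame with columns `node_id`, `timestamp`, `channel`,
#'   `value` covering at least two nodes on a common time base (such as
#'   stacked [packets_to_series()] outputs).
#' @param reference `"mean"` (cross-node mean per interval) or a data frame
#'   `timestamp, channel, reference` of known applied values.
#' @param relative_method `"per_interval"` (relative errors formed per
#'   interval, then time-averaged; the default) or `"from_summary"`
#'   (time-averaged absolute errors divided by the time-averaged reference).
#' @return An object of class `repeatability_report`: list with `intervals`
#'   (per timestamp and channel: reference, mean and SD of absolute errors,
#'   and their relative forms) and `summary` (per channel time averages).
#' @export
repeatability_report <- function(series, reference = "mean",
                                 relative_method = c("per_interval",
                                                     "from_summary")) {
  relative_method <- match.arg(relative_method)
  if (length(unique(series$node_id)) < 2L)
    stop_barnsense("repeatability needs at least two nodes",
                   "barnsense_insufficient_replication")
  key <- interaction(series$channel, series$timestamp, drop = TRUE)
  rows <- lapply(split(series, key), function(g) {
    ref <- if (identical(reference, "mean")) mean(g$value) else {
      m <- reference$reference[reference$timestamp == g$timestamp[1] &
                                 reference$channel == g$channel[1]]
      if (!length(m)) return(NULL)
      m[1]
    }
    err <- abs(g$value - ref)
    data.frame(channel = g$channel[1], timestamp = g$timestamp[1],
               reference = ref, n_nodes = length(err),
               mean_abs = mean(err),
               sd_abs = if (length(err) > 1) stats::sd(err) else NA_real_,
               stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, Filter(Negate(is.null), rows))
  intervals <- intervals[order(intervals$channel, intervals$timestamp), ]
  rownames(intervals) <- NULL
  intervals$mean_rel <- ifelse(intervals$reference != 0,
                               intervals$mean_abs / abs(intervals$reference),
                               NA_real_)
  intervals$sd_rel <- ifelse(intervals$reference != 0,
                             intervals$sd_abs / abs(intervals$reference),
                             NA_real_)
  summ <- do.call(rbind, lapply(split(intervals, intervals$channel),
                                function(g) {
    out <- data.frame(channel = g$channel[1],
                      mean_abs = mean(g$mean_abs),
                      sd_abs = mean(g$sd_abs, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    if (relative_method == "per_interval") {
      out$mean_rel <- mean(g$mean_rel, na.rm = TRUE)
      out$sd_rel <- mean(g$sd_rel, na.rm = TRUE)
    } else {
      mref <- mean(abs(g$reference))
      out$mean_rel <- if (mref > 0) out$mean_abs / mref else NA_real_
      out$sd_rel <- if (mref > 0) out$sd_abs / mref else NA_real_
    }
    out
  }))
  rownames(summ) <- NULL
  structure(list(intervals = intervals, summary = summ,
                 reference = if (identical(reference, "mean"))
                   "cross-node mean" else "known applied",
                 relative_method = relative_method),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("Repeatability report (reference: %s)\n", x$reference))
  s <- x$summary
  s$mean_rel <- sprintf("%.2f%%", 100 * s$mean_rel)
  s$sd_rel <- sprintf("%.2f%%", 100 * s$sd_rel)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a repeatability summary as CSV
#'
#' Columns mirror the absolute/relative, mean/SD layout of a sensor error
#' table.
#'
#' @param report A [repeatability_report()].
#' @param path Output CSV path.
#' @export
write_repeatability_csv <- function(report, path) {
  utils::write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}
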