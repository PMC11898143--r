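#' Sensor channel specifications
#'
#' `channel_spec()` describes one physical sensor channel: measurement range,
#' printed accuracy and electrical interface. `default_channel_specs()`
#' returns the full complement of the multi-sensor node: temperature and
#' humidity (CMOS), sound pressure (MEMS microphone), illuminance
#' (photodiode), H2S and NH3 (electrochemical), CO2 (NDIR), VOC/NOx index
#' and four particulate-matter fractions (laser scattering).
#'
#' Accuracy may be absolute (channel units) and/or relative (fraction of the
#' reading); where both are given the larger applies at a given reading, as
#' for the CO2 channel (+-30 ppm or +-3 %).
#'
#' @param channel Channel name, one of `temp`, `rh`, `sound`, `lux`, `h2s`,
#'   `nh3`, `co2`, `voc`, `nox`, `pm1`, `pm25`, `pm4`, `pm10`.
#' @param range_low,range_high Measurement range in channel units.
#' @param accuracy_abs Absolute accuracy, channel units (NA if none).
#' @param accuracy_rel Relative accuracy as a fraction (NA if none).
#' @param interface `"analog"` or `"digital"`.
#' @return A one-row data frame; `default_channel_specs()` binds one row per
#'   channel.
#' @export
channel_spec <- function(channel, range_low, range_high,
                         accuracy_abs = NA_real_, accuracy_rel = NA_real_,
                         interface = c("analog", "digital")) {
  interface <- match.arg(interface)
  if (!channel %in% CHANNELS)
    stop_barnsense(sprintf("unknown channel '%s'", channel),
                   "barnsense_config_error")
  if (range_low >= range_high)
    stop_barnsense("range_low must be below range_high", "barnsense_config_error")
  if (!is.na(accuracy_abs) && accuracy_abs <= 0)
    stop_barnsense("accuracy must be positive", "barnsense_config_error")
  if (!is.na(accuracy_rel) && accuracy_rel <= 0)
    stop_barnsense("accuracy must be positive", "barnsense_config_error")
  data.frame(channel = channel, range_low = range_low, range_high = range_high,
             accuracy_abs = accuracy_abs, accuracy_rel = accuracy_rel,
             interface = interface, stringsAsFactors = FALSE)
}

#' @rdname channel_spec
#' @export
default_channel_specs <- function() {
  rbind(
    channel_spec("temp", -10, 60, accuracy_abs = 0.2, interface = "digital"),
    channel_spec("rh", 0, 100, accuracy_abs = 2, interface = "digital"),
    channel_spec("sound", 30, 130, accuracy_rel = 0.02, interface = "analog"),
    channel_spec("lux", 0, 128000, accuracy_rel = 0.30, interface = "analog"),
    channel_spec("h2s", 0, 10, accuracy_rel = 0.10, interface = "analog"),
    channel_spec("nh3", 0, 100, accuracy_rel = 0.10, interface = "analog"),
    channel_spec("co2", 400, 10000, accuracy_abs = 30, accuracy_rel = 0.03,
                 interface = "digital"),
    channel_spec("voc", 500, 10000, accuracy_rel = 0.0003, interface = "analog"),
    channel_spec("nox", 50, 650, accuracy_rel = 0.001, interface = "analog"),
    channel_spec("pm1", 0, 1000, accuracy_abs = 10, interface = "digital"),
    channel_spec("pm25", 0, 1000, accuracy_abs = 10, interface = "digital"),
    channel_spec("pm4", 0, 1000, accuracy_abs = 25, interface = "digital"),
    channel_spec("pm10", 0, 1000, accuracy_abs = 25, interface = "digital"))
}

#' Sampling policies
#'
#' `sampling_policy()` states how often a channel is read and which window
#' statistics it reports. Firmware defaults: electrochemical gases and sound
#' every 10 s; temperature, humidity, CO2 and illuminance every 60 s;
#' particulate matter and VOC/NOx every 15 min, reported in whichever 10-min
#' window the measurement completes. All channels report into 10-min packets.
#'
#' @param channel Channel name.
#' @param sample_period Sampling period in seconds: 10, 60 or 900.
#' @param stats Subset of `c("avg", "min", "max")`; sound must include both
#'   `"avg"` and `"max"`.
#' @param report_period Reporting (window) period in seconds; fixed at 600.
#' @return A data frame with one row per channel policy.
#' @export
sampling_policy <- function(channel, sample_period,
                            stats = c("avg", "min", "max"),
                            report_period = 600) {
  if (!channel %in% CHANNELS)
    stop_barnsense(sprintf("unknown channel '%s'", channel),
                   "barnsense_config_error")
  if (!sample_period %in% c(10, 60, 900))
    stop_barnsense("sample_period must be one of 10, 60, 900 s",
                   "barnsense_config_error")
  if (report_period != 600)
    stop_barnsense("report_period is fixed at 600 s", "barnsense_config_error")
  stats <- match.arg(stats, several.ok = TRUE)
  if (channel == "sound" && !all(c("avg", "max") %in% stats))
    stop_barnsense("sound must report both avg and max", "barnsense_config_error")
  data.frame(channel = channel, sample_period = sample_period,
             report_period = report_period,
             stats = paste(stats, collapse = "+"), stringsAsFactors = FALSE)
}

#' @rdname sampling_policy
#' @export
default_sampling_policies <- function() {
  rbind(
    sampling_policy("temp", 60),
    sampling_policy("rh", 60),
    sampling_policy("sound", 10, c("avg", "max")),
    sampling_policy("lux", 60),
    sampling_policy("h2s", 10),
    sampling_policy("nh3", 10),
    sampling_policy("co2", 60),
    sampling_policy("voc", 900, "avg"),
    sampling_policy("nox", 900, "avg"),
    sampling_policy("pm1", 900, "avg"),
    sampling_policy("pm25", 900, "avg"),
    sampling_policy("pm4", 900, "avg"),
    sampling_policy("pm10", 900, "avg"))
}

#' Simulate one sensor node reading a ground-truth zone
#'
#' Samples each channel of the zone's ground truth at the channel's native
#' period through a simple sensor transfer function: additive Gaussian noise
#' with standard deviation equal to half the printed accuracy (the accuracy
#' is read as a 2-sigma half-width), followed by saturation at the sensor
#' range limits. Where both absolute and relative accuracies exist, the
#' larger applies at the current reading.
#'
#' @param truth A [make_truth()] result.
#' @param zone Zone identifier present in `truth` (or `"outdoor"`).
#' @param specs Channel specifications, see [default_channel_specs()].
#' @param policies Sampling policies, see [default_sampling_policies()].
#' @param noise_seed Integer seed for the measurement noise stream.
#' @param node_id Integer node identifier (0..65535).
#' @param noise Set `FALSE` for an ideal (noiseless) sensor; range clipping
#'   still applies.
#' @return A data frame of class `raw_samples` with columns `node_id`,
#'   `channel`, `timestamp` (seconds since the truth start) and `value`.
#' @export
simulate_node <- function(truth, zone, specs = default_channel_specs(),
                          policies = default_sampling_policies(),
                          noise_seed = 1, node_id = 1L, noise = TRUE) {
  if (!inherits(truth, "barn_truth"))
    stop_barnsense("truth must be a barn_truth", "barnsense_config_error")
  zf <- if (identical(zone, "outdoor")) truth$outdoor else truth$zones[[zone]]
  if (is.null(zf))
    stop_barnsense(sprintf("zone '%s' not found in ground truth", zone),
                   "barnsense_lookup_error")
  if (anyDuplicated(policies$channel))
    stop_barnsense("one policy per channel", "barnsense_config_error")
  node_id <- as.integer(node_id)

  with_seed(noise_seed, {
    parts <- lapply(seq_len(nrow(policies)), function(i) {
      ch <- policies$channel[i]
      per <- policies$sample_period[i]
      sp <- specs[specs$channel == ch, , drop = FALSE]
      if (nrow(sp) != 1L)
        stop_barnsense(sprintf("no channel spec for '%s'", ch),
                       "barnsense_config_error")
      idx <- which(zf$time %% per == 0)
      v <- zf[[ch]][idx]
      if (noise) {
        sd <- pmax(ifelse(is.na(sp$accuracy_abs), 0, sp$accuracy_abs),
                   ifelse(is.na(sp$accuracy_rel), 0, sp$accuracy_rel * abs(v))) / 2
        v <- v + stats::rnorm(length(v), 0, sd)
      }
      v <- pmin(sp$range_high, pmax(sp$range_low, v))
      data.frame(node_id = node_id, channel = ch, timestamp = zf$time[idx],
                 value = v, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    class(out) <- c("raw_samples", class(out))
    out
  })
}

#' Aggregate raw samples into 10-minute packet records
#'
#' `aggregate_window()` condenses the samples of one 600 s window into a
#' packet record carrying, for each channel with data in the window, the
#' arithmetic mean, minimum and maximum. Slow channels (15-min particulate
#' and VOC readings) are present only in windows where a measurement
#' completed; a mandatory channel with no samples has its presence flag
#' cleared with a warning. `aggregate_packets()` maps a whole sample stream
#' onto its consecutive windows.
#'
#' @param samples A `raw_samples` data frame (see [simulate_node()]).
#' @param policies Sampling policies (used for presence bookkeeping).
#' @param window_start Window start, seconds; must be a multiple of 600.
#' @param node_id,slot Telemetry identity stamped on the packet.
#' @return `aggregate_window()`: a `packet_record`; `aggregate_packets()`:
#'   a list of them, one per window with any data.
#' @export
aggregate_window <- function(samples, policies = default_sampling_policies(),
                             window_start, node_id = samples$node_id[1],
                             slot = 0L) {
  if (window_start %% 600 != 0)
    stop_barnsense("window_start must be a multiple of 600 s",
                   "barnsense_config_error")
  w <- samples[samples$timestamp >= window_start &
                 samples$timestamp < window_start + 600, , drop = FALSE]
  stats_list <- list()
  for (i in seq_len(nrow(policies))) {
    ch <- policies$channel[i]
    v <- w$value[w$channel == ch]
    if (!length(v)) {
      if (policies$sample_period[i] < 900)   # fast channel should have data
        warning(sprintf("no samples for mandatory channel '%s' in window %d; presence flag cleared",
                        ch, window_start), call. = FALSE)
      next
    }
    stats_list[[ch]] <- c(avg = mean(v), min = min(v), max = max(v))
  }
  packet_record(node_id = node_id, slot = slot, window_start = window_start,
                stats = stats_list)
}

#' @rdname aggregate_window
#' @export
aggregate_packets <- function(samples, policies = default_sampling_policies(),
                              node_id = samples$node_id[1], slot = 0L) {
  w <- floor(samples$timestamp / 600) * 600
  idx <- list(w = w, ch = samples$channel)
  avg <- tapply(samples$value, idx, mean)
  mn <- tapply(samples$value, idx, min)
  mx <- tapply(samples$value, idx, max)
  windows <- sort(as.numeric(rownames(avg)))
  chans <- colnames(avg)
  fast <- policies$channel[policies$sample_period < 900]
  lapply(windows, function(ws) {
    key <- as.character(ws)
    present <- chans[!is.na(avg[key, ])]
    for (ch in setdiff(fast, present))
      warning(sprintf("no samples for mandatory channel '%s' in window %d; presence flag cleared",
                      ch, ws), call. = FALSE)
    stats_list <- lapply(stats::setNames(present, present), function(ch)
      c(avg = avg[key, ch], min = mn[key, ch], max = mx[key, ch]))
    packet_record(node_id = node_id, slot = slot, window_start = ws,
                  stats = stats_list)
  })
}

#' Construct a packet record
#'
#' The unit of telemetry: one node's 10-minute aggregate with per-channel
#' average, minimum and maximum for every channel present in the window.
#'
#' @param node_id Integer node id (0..65535).
#' @param slot Assigned time slot (0..599).
#' @param window_start Window start in seconds (multiple of 600, >= 0).
#' @param stats Named list keyed by channel; each element a numeric vector
#'   with names `avg`, `min`, `max` satisfying `min <= avg <= max`.
#' @return An object of class `packet_record`.
#' @export
packet_record <- function(node_id, slot, window_start, stats) {
  if (window_start %% 600 != 0 || window_start < 0)
    stop_barnsense("window_start must be a non-negative multiple of 600 s",
                   "barnsense_config_error")
  bad <- !names(stats) %in% CHANNELS
  if (any(bad))
    stop_barnsense(sprintf("unknown channels: %s",
                           paste(names(stats)[bad], collapse = ", ")),
                   "barnsense_config_error")
  for (ch in names(stats)) {
    s <- stats[[ch]]
    if (!all(c("avg", "min", "max") %in% names(s)))
      stop_barnsense("each channel needs avg, min, max", "barnsense_config_error")
    if (s[["min"]] > s[["avg"]] + 1e-9 || s[["avg"]] > s[["max"]] + 1e-9)
      stop_barnsense(sprintf("channel '%s' violates min <= avg <= max", ch),
                     "barnsense_config_error")
  }
  structure(list(node_id = as.integer(node_id), slot = as.integer(slot),
                 window_start = as.numeric(window_start),
                 stats = stats[order(match(names(stats), CHANNELS))]),
            class = "packet_record")
}

#' @export
print.packet_record <- function(x, ...) {
  cat(sprintf("packet: node %d slot %d window %s\n", x$node_id, x$slot,
              format_iso8601(x$window_start)))
  for (ch in names(x$stats))
    cat(sprintf("  %-5s avg %.4g  min %.4g  max %.4g\n", ch,
                x$stats[[ch]][["avg"]], x$stats[[ch]][["min"]],
                x$stats[[ch]][["max"]]))
  invisible(x)
}

#' Assign time-division slots to nodes
#'
#' The uplink period is 10 minutes divided into 600 one-second slots; each
#' node gets one slot, assigned deterministically in registration order.
#'
#' @param node_ids Ordered vector of node identifiers (at most 600, unique).
#' @return Named integer vector mapping node id to slot (0-based).
#' @examples
#' assign_slots(c("A", "B", "C"))
#' @export
assign_slots <- function(node_ids) {
  if (anyDuplicated(node_ids))
    stop_barnsense("node ids must be unique", "barnsense_config_error")
  if (length(node_ids) > 600)
    stop_barnsense("at most 600 nodes fit the 600 one-second slots",
                   "barnsense_capacity_error")
  stats::setNames(seq_along(node_ids) - 1L, as.character(node_ids))
}
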