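#' Gateway store-and-forward buffer
#'
#' Models the gateway's double-buffered, loss-resilient delivery path.
#' Incoming packets are buffered in RAM; when the RAM queue exceeds its
#' capacity the oldest messages spill to a persistent flash buffer. While the
#' uplink is up, buffered messages are flushed (flash first, then RAM) to the
#' delivered ledger. A power cycle clears the RAM buffer but not flash, and
#' at power-on any flash-buffered messages are forwarded as soon as the link
#' allows. Messages keep their origin timestamps, and a delivered ledger
#' keyed by `(node_id, window_start)` drops duplicates, giving exactly-once
#' delivery for every message that survives buffering.
#'
#' @param ram_capacity Maximum RAM queue length before spilling to flash.
#' @return `gateway_state()` returns a fresh state of class `gateway_state`.
#' @seealso [gateway_step()]
#' @export
gateway_state <- function(ram_capacity = 64) {
  structure(list(ram = list(), flash = list(), delivered = list(),
                 keys = character(0), link_up = FALSE,
                 ram_capacity = ram_capacity),
            class = "gateway_state")
}

#' Advance the gateway state by one event
#'
#' @param state A [gateway_state()].
#' @param event One of `"receive"` (with `msg`), `"link_up"`, `"link_down"`,
#'   `"power_cycle"`. All events are legal in all states.
#' @param msg For `"receive"`: a message with `node_id` and `window_start`
#'   fields (for example a [packet_record()]).
#' @return The new `gateway_state`.
#' @examples
#' st <- gateway_state()
#' p <- packet_record(1L, 0L, 0, list(temp = c(avg = 20, min = 19, max = 21)))
#' st <- gateway_step(st, "receive", p)     # link down: buffered
#' st <- gateway_step(st, "link_up")        # flushed to delivered
#' length(delivered_messages(st))           # 1
#' @export
gateway_step <- function(state, event = c("receive", "link_up", "link_down",
                                          "power_cycle"), msg = NULL) {
  event <- match.arg(event)
  if (event == "receive") {
    if (is.null(msg$node_id) || is.null(msg$window_start))
      stop_barnsense("message needs node_id and window_start",
                     "barnsense_config_error")
    key <- msg_key(msg)
    buffered <- c(vapply(state$ram, msg_key, character(1)),
                  vapply(state$flash, msg_key, character(1)))
    if (!(key %in% state$keys) && !(key %in% buffered)) {
      state$ram[[length(state$ram) + 1L]] <- msg
      while (length(state$ram) > state$ram_capacity) {   # spill oldest
        state$flash[[length(state$flash) + 1L]] <- state$ram[[1L]]
        state$ram[[1L]] <- NULL
      }
    }
  } else if (event == "link_up") {
    state$link_up <- TRUE
  } else if (event == "link_down") {
    state$link_up <- FALSE
  } else if (event == "power_cycle") {
    state$ram <- list()       # volatile buffer lost; flash survives
  }
  if (state$link_up) state <- gateway_flush(state)
  state
}

gateway_flush <- function(state) {
  for (m in c(state$flash, state$ram)) {
    key <- msg_key(m)
    if (!(key %in% state$keys)) {
      state$delivered[[length(state$delivered) + 1L]] <- m
      state$keys <- c(state$keys, key)
    }
  }
  state$flash <- list()
  state$ram <- list()
  state
}

msg_key <- function(msg) paste(msg$node_id, msg$window_start, sep = "/")

#' @rdname gateway_step
#' @export
delivered_messages <- function(state) state$delivered

#' Decode packet records into a device time series
#'
#' Turns a list of packets from one or more nodes into a tidy long series at
#' 10-minute resolution, carrying the chosen window statistic per channel.
#'
#' @param packets List of [packet_record()]s.
#' @param stat Which packet statistic becomes `value`: `"avg"` (default,
#'   used for cloud aggregates), `"min"` or `"max"` (kept for exceedance
#'   checks).
#' @return A data frame of class `device_series` with columns `node_id`,
#'   `timestamp` (window start, seconds), `channel`, `value` and `coverage`
#'   (1 for a decoded packet), and attribute `resolution` = 600 s.
#' @export
packets_to_series <- function(packets, stat = c("avg", "min", "max")) {
  stat <- match.arg(stat)
  rows <- lapply(packets, function(p) {
    if (!length(p$stats)) return(NULL)
    data.frame(node_id = p$node_id, timestamp = p$window_start,
               channel = names(p$stats),
               value = vapply(p$stats, `[[`, numeric(1), stat),
               coverage = 1, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- out[order(out$node_id, out$channel, out$timestamp), ]
  rownames(out) <- NULL
  device_series(out, resolution = 600)
}

device_series <- function(df, resolution) {
  attr(df, "resolution") <- resolution
  class(df) <- unique(c("device_series", class(df)))
  df
}

#' Resample a device series to hourly or daily resolution
#'
#' Bins are arithmetic means of the available finer-resolution records. A
#' bin with coverage (fraction of expected records present) below
#' `min_coverage` is marked missing (`NA` value); coverage is always
#' recorded.
#'
#' @param series A `device_series` (for example from [packets_to_series()]).
#' @param target `"hourly"` or `"daily"`.
#' @param min_coverage Coverage threshold below which a bin is missing
#'   (default 0.5).
#' @return A `device_series` at the target resolution with columns
#'   `node_id`, `timestamp` (bin start), `channel`, `value`, `coverage`.
#' @export
resample_series <- function(series, target = c("hourly", "daily"),
                            min_coverage = 0.5) {
  target <- match.arg(target)
  bin <- if (target == "hourly") 3600 else 86400
  res <- attr(series, "resolution")
  if (is.null(res))
    stop_barnsense("series lacks a resolution attribute", "barnsense_config_error")
  if (res >= bin)
    stop_barnsense("input must be at finer resolution than the target",
                   "barnsense_resolution_error")
  expected <- bin / res
  ok <- !is.na(series$value)
  tsbin <- floor(series$timestamp / bin) * bin
  key <- paste(series$node_id, series$channel, tsbin, sep = "\r")
  groups <- split(which(ok), key[ok])
  all_keys <- unique(key)
  rows <- lapply(all_keys, function(k) {
    idx <- groups[[k]]
    n <- length(idx)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(node_id = utils::type.convert(parts[1], as.is = TRUE),
               timestamp = as.numeric(parts[3]), channel = parts[2],
               value = if (n / expected >= min_coverage) mean(series$value[idx])
                       else NA_real_,
               coverage = n / expected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$node_id, out$channel, out$timestamp), ]
  rownames(out) <- NULL
  device_series(out, resolution = bin)
}

#' Temperature-humidity index (THI)
#'
#' The standard dairy heat-stress index combining dry-bulb temperature and
#' relative humidity:
#' `THI = (1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26)`.
#' Values above ~68 indicate the onset of heat stress in dairy cattle.
#'
#' @param temp Air temperature, degC.
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @return THI (dimensionless), vectorized over inputs.
#' @examples
#' compute_thi(25, 50)  # 71.775
#' @export
compute_thi <- function(temp, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop_barnsense("relative humidity must lie in [0, 100]",
                   "barnsense_domain_error")
  (1.8 * temp + 32) - (0.55 - 0.0055 * rh) * (1.8 * temp - 26)
}

#' Trailing rolling aggregate of a device series
#'
#' Right-aligned trailing-window statistic (such as the 24 h running mean
#' maintained by the cloud rule chain); values are missing until the window
#' is filled.
#'
#' @param series A `device_series`.
#' @param window_hours Window length in hours; at least one series step.
#' @param stat `"mean"`, `"max"` or `"min"`.
#' @return A `device_series` with `value` replaced by the rolling statistic.
#' @export
rolling_aggregate <- function(series, window_hours,
                              stat = c("mean", "max", "min")) {
  stat <- match.arg(stat)
  res <- attr(series, "resolution")
  width <- round(window_hours * 3600 / res)
  if (width < 1)
    stop_barnsense("window shorter than the series resolution",
                   "barnsense_resolution_error")
  fun <- switch(stat, mean = mean, max = max, min = min)
  parts <- split(series, list(series$node_id, series$channel), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) {
    g <- g[order(g$timestamp), ]
    g$value <- if (nrow(g) >= width)
      zoo::rollapply(g$value, width, fun, align = "right", fill = NA)
    else rep(NA_real_, nrow(g))
    g
  }))
  out <- out[order(out$node_id, out$channel, out$timestamp), ]
  rownames(out) <- NULL
  device_series(out, resolution = res)
}

#' Write and read a tidy device-series CSV
#'
#' Columns `node_id,timestamp,channel,value,coverage` with ISO-8601
#' timestamps.
#'
#' @param series A `device_series`.
#' @param path CSV path.
#' @param start POSIXct epoch for second offsets (default Unix epoch).
#' @export
write_series_csv <- function(series, path,
                             start = as.POSIXct("1970-01-01", tz = "UTC")) {
  out <- series
  out$timestamp <- format_iso8601(as.numeric(start) + out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param resolution Series resolution in seconds, recorded on read.
#' @export
read_series_csv <- function(path, resolution,
                            start = as.POSIXct("1970-01-01", tz = "UTC")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.numeric(as.POSIXct(df$timestamp,
                                        format = "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC")) - as.numeric(start)
  device_series(df, resolution = resolution)
}
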