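# Internal helpers shared across modules.

# Channel order is load-bearing: it fixes the presence-bitmap bit positions in
# the telemetry codec, so it must never be reordered.
CHANNELS <- c("temp", "rh", "sound", "lux", "h2s", "nh3", "co2",
              "voc", "nox", "pm1", "pm25", "pm4", "pm10")

GAS_CHANNELS <- c("nh3", "co2", "h2s")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_barnsense <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "barnsense_error")))
}

# Parse "HH:MM" to fractional hours of day.
parse_hhmm <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    h <- as.numeric(p[[1]]); m <- as.numeric(p[[2]])
    if (is.na(h) || is.na(m) || h < 0 || h >= 24 || m < 0 || m >= 60)
      stop_barnsense(sprintf("invalid time of day '%s'", paste(p, collapse = ":")),
                     "barnsense_config_error")
    h + m / 60
  }, numeric(1))
}

format_iso8601 <- function(seconds, origin = "1970-01-01") {
  format(as.POSIXct(seconds, origin = origin, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}
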