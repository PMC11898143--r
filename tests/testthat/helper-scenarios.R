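# Shared scenario builders for the test suite.

# Dairy-scale steady scenario: open barn, herd-driven CO2, constant climate.
# Sized so indoor concentrations sit near realistic open-barn levels
# (CO2 ~ 610 ppm, NH3 ~ 1.7 ppm over a 420/0.1 ppm background).
dairy_herd <- function() herd_config(140, body_mass = 650, milk_yield = 37)

dairy_truth <- function(seed = 1, days = 1, nh3_source = 233,
                        ventilation = 210000, volume = 5000,
                        mean_temp = 17, outdoor_nh3 = 0.1, outdoor_co2 = 420,
                        herd = dairy_herd(), init = "steady") {
  co2_src <- co2_production(herd, temp = mean_temp + 3)
  z <- zone_config("barn", volume = volume, ventilation_rate = ventilation,
                   nh3_source = nh3_source, co2_source = co2_src)
  cl <- climate_config(mean_temp = mean_temp, diurnal_amplitude = 0,
                       mean_rh = 65, outdoor_nh3 = outdoor_nh3,
                       outdoor_co2 = outdoor_co2, rh_noise_sd = 0)
  make_truth(z, cl, event_schedule(character(0)), duration_days = days,
             seed = seed, init = init)
}

# Policies restricted to the channels the emission pipeline consumes.
gas_policies <- function() {
  p <- default_sampling_policies()
  p[p$channel %in% c("temp", "rh", "nh3", "co2"), ]
}

# Simulate three barn nodes plus the background node, aggregate to packets,
# resample hourly, and run the tracer-gas estimator.
run_emission_pipeline <- function(truth, herd = dairy_herd(), noise = FALSE,
                                  seed = 1, n_indoor = 3) {
  pol <- gas_policies()
  hourly_for <- function(zone, node_id, noise_seed) {
    s <- simulate_node(truth, zone, policies = pol, noise_seed = noise_seed,
                       node_id = node_id, noise = noise)
    resample_series(packets_to_series(aggregate_packets(s, pol)), "hourly")
  }
  indoor <- lapply(seq_len(n_indoor), function(i)
    hourly_for(names(truth$zones)[1], i, seed * 1000 + i))
  outdoor <- hourly_for("outdoor", 99L, seed * 1000 + 99)
  estimate_emissions(indoor, outdoor, herd)
}

# Random packet record on the quantized (codec-representable) domain.
random_packet <- function() {
  n_ch <- sample(seq_along(barnsense:::CHANNELS), 1)
  chans <- sample(barnsense:::CHANNELS, n_ch)
  stats <- lapply(stats::setNames(chans, chans), function(ch) {
    sc <- barnsense:::CODEC_SCALE[[ch]]
    q <- sort(sample.int(65535, 3) - 32769L)   # three int16 values
    v <- q / sc
    c(avg = v[2], min = v[1], max = v[3])
  })
  packet_record(node_id = sample.int(65535, 1), slot = sample.int(600, 1) - 1L,
                window_start = 600 * (sample.int(10000, 1) - 1L),
                stats = stats)
}

# Constant-field truth stub: every channel flat at the given levels, used for
# sensor-noise and repeatability studies where gas dynamics are irrelevant.
constant_truth <- function(levels, days = 1, dt = 10) {
  n <- as.integer(days * 86400 / dt)
  df <- data.frame(time = (seq_len(n) - 1) * dt)
  for (ch in barnsense:::CHANNELS)
    df[[ch]] <- rep(if (ch %in% names(levels)) levels[[ch]] else 0, n)
  structure(list(zones = list(lab = df), outdoor = df,
                 params = list(), seed = 0L, dt = dt,
                 start = as.POSIXct("2023-06-01", tz = "UTC")),
            class = "barn_truth")
}

# Reference levels for a bench/lab check, one per channel, mid-range.
lab_levels <- function() {
  c(temp = 22, rh = 55, sound = 60, lux = 800, h2s = 2, nh3 = 20,
    co2 = 800, voc = 900, nox = 200, pm1 = 10, pm25 = 15, pm4 = 20, pm10 = 30)
}
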