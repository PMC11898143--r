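# barnsense

Simulation and analytics for multi-sensor environmental monitoring of
livestock housing.

Air quality inside barns drives both animal welfare and a farm's
environmental footprint: welfare guidance flags housing as inadequate
when NH3 exceeds 10 ppm, CO2 3000 ppm or H2S 0.5 ppm, and ammonia
emitted from excreta is a regulated pollutant. Low-cost IoT multi-sensor
nodes make continuous, multi-point monitoring affordable — but the chain
from an electrochemical cell's nanoamp output to a defensible emission
estimate involves calibration, multi-rate sampling, lossy telemetry,
aggregation and a tracer-gas model, and every link needs validation.
barnsense implements that whole chain against a synthetic barn with known
ground truth, so each step can be tested by parameter recovery. It is
aimed at people designing or validating such monitoring systems:
precision-livestock researchers, sensor-network engineers, and anyone who
wants to know how much of an emission estimate's error budget each link
consumes.

## What it provides

* **Synthetic barn** (`make_truth`): per-zone well-mixed gas mass balance
  `V dC/dt = S(t) + Q(t)(C_out − C)` integrated exactly on a 10 s grid,
  diurnal temperature, feeding-event source pulses, an outdoor background
  point, and a fully recorded parameter set per seed.
* **Virtual sensor node** (`simulate_node`, `aggregate_packets`,
  `encode_packet`/`decode_packet`, `assign_slots`): 13 channels at their
  native rates, Gaussian noise with SD = printed accuracy / 2, range
  saturation, 10-minute avg/min/max records, a CRC-protected binary wire
  format and 600 one-second uplink slots.
* **Calibration** (`span_calibrate`, `zero_calibrate`,
  `apply_calibration`, `repeatability_report`): two-point span fits for
  electrochemical sensors, offset-only CO2 calibration, and multi-device
  repeatability statistics (mean and SD of absolute errors per interval,
  absolute and relative summaries).
* **Gateway and aggregation** (`gateway_step`, `resample_series`,
  `compute_thi`, `rolling_aggregate`): RAM→flash store-and-forward
  buffering with exactly-once delivery, hourly/daily resampling with a
  coverage rule, the temperature-humidity index
  `THI = (1.8T + 32) − (0.55 − 0.0055·RH)(1.8T − 26)`, and trailing
  24 h aggregates.
* **Welfare analytics** (`assess_thresholds`, `uniformity_test`,
  `diurnal_profile`, `correlate`, `spatial_map`): limit exceedance,
  ANOVA + Tukey uniformity comparison with compact letter display,
  hour-of-day profiles with standard errors, Pearson correlations and
  inverse-distance-weighted concentration maps.
* **Emission estimation** (`co2_production`, `nh3_emission`,
  `estimate_emissions`): the CO2 tracer-gas balance

  ```
  E_NH3 = P_CO2 · (C_NH3,barn − C_NH3,out) / (C_CO2,barn − C_CO2,out)
  ```

  with herd metabolic CO2 from the CIGR/VERA heat-production form
  `Φ_tot = 5.6 m^0.75 + 22 Y + 1.6e-5 p³` W per head, temperature
  correction `(1000 + 4(20 − T))/1000`, and 0.185 m³ h⁻¹ CO2 per
  heat-producing unit (1000 W), computed hourly and summarized per
  animal per day.

## Worked example: recover a known emission from simulated telemetry

A 140-cow dairy herd (650 kg, 37 kg milk/day) in a steady barn with an
NH3 source of 233 g h⁻¹, monitored by three indoor nodes and one outdoor
background node; the estimator sees only noisy, packetized sensor data.

```r
library(barnsense)

herd <- herd_config(n_animals = 140, body_mass = 650, milk_yield = 37)
barn <- zone_config("barn", volume = 5000, ventilation_rate = 210000,
                    nh3_source = 233,
                    co2_source = co2_production(herd, temp = 20))
climate <- climate_config(mean_temp = 17, diurnal_amplitude = 0,
                          outdoor_nh3 = 0.1, outdoor_co2 = 420)
truth <- make_truth(barn, climate, event_schedule(character(0)),
                    duration_days = 1, seed = 42, init = "steady")

pol <- default_sampling_policies()
pol <- pol[pol$channel %in% c("temp", "rh", "nh3", "co2"), ]
hourly <- function(zone, id) {
  s <- simulate_node(truth, zone, policies = pol, noise_seed = id,
                     node_id = id)
  resample_series(packets_to_series(aggregate_packets(s, pol)), "hourly")
}
indoor  <- lapply(1:3, function(i) hourly("barn", i))
outdoor <- hourly("outdoor", 99L)

estimate_emissions(indoor, outdoor, herd)
#> NH3 emission estimate (CO2 tracer), 24 hour(s), 1 day(s)
#>   per-animal daily emission: 40.0 g animal-1 day-1 (mean over 1 day(s))
#>   invalid hours (non-positive CO2 difference): 0
```

The true value is `233 × 24 / 140 = 39.94` g animal⁻¹ day⁻¹: the
estimator recovers it through the full noisy telemetry chain. Typical
reported dairy-housing NH3 emissions sit in the 30–45 g animal⁻¹ day⁻¹
range, so the scenario is realistically scaled.

Welfare screening of recorded device means works directly on a table:

```r
means <- data.frame(node_id = paste0("ID", 1:6), channel = "nh3",
                    value = c(7.3, 6.5, 9.5, 11.4, 7.9, 10.4))
assess_thresholds(means)
#> Welfare threshold assessment
#>  node_id channel mean frac_above limit exceeds
#>      ID1     nh3  7.3          0    10   FALSE
#>      ID2     nh3  6.5          0    10   FALSE
#>      ID3     nh3  9.5          0    10   FALSE
#>      ID4     nh3 11.4          1    10    TRUE
#>      ID5     nh3  7.9          0    10   FALSE
#>      ID6     nh3 10.4          1    10    TRUE
#> 2 device-channel(s) with period mean above the limit

compute_thi(25, 50)
#> [1] 71.775
```

Two of the six monitoring points exceed the 10 ppm NH3 welfare limit —
the pattern a spatial `spatial_map()` then localizes to the
poorly-ventilated corner of the room.

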