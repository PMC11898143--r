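test_that("steady_state_conc matches the closed form and rejects bad ventilation", {
  expect_equal(steady_state_conc(0, 1000, 0.001), 0.001)
  expect_equal(steady_state_conc(50, 10000, 0), 0.005)
  expect_equal(steady_state_conc(100, 5000, 0.0004), 0.0204)
  expect_error(steady_state_conc(1, 0), class = "barnsense_domain_error")
  expect_error(steady_state_conc(1, -10), class = "barnsense_domain_error")
})

test_that("discrete mass balance matches the analytic solution of the linear ODE", {
  v <- 3000; q <- 9000; s <- 50; c_out <- 2e-4
  z <- zone_config("z", v, q, nh3_source = s)
  cl <- climate_config(diurnal_amplitude = 0, outdoor_nh3 = 0.1, rh_noise_sd = 0)
  tr <- make_truth(z, cl, event_schedule(character(0)), duration_days = 1,
                   seed = 1, init = "background")
  zf <- tr$zones$z
  c0 <- zf$nh3_gm3[1]
  css <- steady_state_conc(s, q, c0)
  t_h <- zf$time / 3600
  analytic <- css + (c0 - css) * exp(-q * t_h / v)
  expect_lt(max(abs(zf$nh3_gm3 - analytic) / css), 1e-9)
  # converges to the steady state once many time constants have elapsed
  tau_h <- v / q
  tail_idx <- which(t_h > 25 * tau_h)
  expect_lt(max(abs(zf$nh3_gm3[tail_idx] - css) / css), 1e-9)
})

test_that("a source-free zone sits at the outdoor background at all times", {
  z <- zone_config("z", 2000, 8000)
  cl <- climate_config(diurnal_amplitude = 0, outdoor_nh3 = 0.2,
                       outdoor_co2 = 450, outdoor_h2s = 0.05,
                       animal_heat_offset = 0)
  tr <- make_truth(z, cl, event_schedule(character(0)), seed = 2)
  zf <- tr$zones$z
  od <- tr$outdoor
  for (g in c("nh3", "co2", "h2s")) {
    expect_equal(zf[[paste0(g, "_gm3")]], od[[paste0(g, "_gm3")]],
                 tolerance = 1e-12)
    # with no animal heat the indoor ppm channel matches the background too
    expect_equal(zf[[g]], od[[g]], tolerance = 1e-9)
  }
})

test_that("concentrations never fall below background and grow with the source", {
  cl <- climate_config(diurnal_amplitude = 4, outdoor_nh3 = 0.1)
  mk <- function(src) {
    z <- zone_config("z", 1500, 6000, nh3_source = src)
    make_truth(z, cl, duration_days = 1, seed = 7)$zones$z$nh3_gm3
  }
  lo <- mk(20); hi <- mk(35)
  bg <- make_truth(zone_config("z", 1500, 6000), cl, seed = 7)$outdoor$nh3_gm3
  expect_true(all(lo >= bg - 1e-10))
  expect_true(all(hi >= lo))
})

test_that("ground truth is bit-reproducible from (config, seed)", {
  z <- zone_config("z", 1000, 5000, nh3_source = 10, co2_source = 2000)
  a <- make_truth(z, seed = 42)
  b <- make_truth(z, seed = 42)
  d <- make_truth(z, seed = 43)
  expect_identical(a$zones, b$zones)
  expect_identical(a$outdoor, b$outdoor)
  expect_false(identical(a$zones$z$rh, d$zones$z$rh))
})

test_that("zones with larger source-to-ventilation ratio are more concentrated", {
  zs <- list(zone_config("low", 1000, 20000, nh3_source = 50),
             zone_config("mid", 1000, 10000, nh3_source = 50),
             zone_config("high", 1000, 10000, nh3_source = 120))
  tr <- make_truth(zs, climate_config(diurnal_amplitude = 0, rh_noise_sd = 0),
                   event_schedule(character(0)), seed = 1, init = "steady")
  m <- vapply(tr$zones, function(z) mean(z$nh3_gm3), numeric(1))
  expect_true(m[["low"]] < m[["mid"]] && m[["mid"]] < m[["high"]])
})

test_that("feeding events raise concentrations inside the event window", {
  z <- zone_config("z", 500, 10000, nh3_source = 100)   # fast time constant
  ev <- event_schedule(c("07:15", "16:30"), multiplier = 2, duration_min = 60)
  tr <- make_truth(z, climate_config(diurnal_amplitude = 0, rh_noise_sd = 0),
                   ev, seed = 1, init = "steady")
  zf <- tr$zones$z
  hod <- (zf$time / 3600) %% 24
  in_evt <- hod >= 7.5 & hod < 8.2        # well inside the 07:15-08:15 pulse
  quiet <- hod >= 2 & hod < 5
  expect_gt(min(zf$nh3_gm3[in_evt]), max(zf$nh3_gm3[quiet]) * 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(zone_config("z", -1, 100), class = "barnsense_config_error")
  expect_error(zone_config("z", 10, 0), class = "barnsense_config_error")
  expect_error(zone_config("z", 10, 100, nh3_source = -1),
               class = "barnsense_config_error")
  expect_error(climate_config(mean_rh = 130), class = "barnsense_config_error")
  expect_error(climate_config(outdoor_co2 = 300), class = "barnsense_config_error")
  expect_error(climate_config(peak_hour = 24), class = "barnsense_config_error")
  expect_error(event_schedule(multiplier = 0.5), class = "barnsense_config_error")
  expect_error(make_truth(zone_config("z", 10, 100), duration_days = 0.2),
               class = "barnsense_config_error")
})

test_that("scenario files round-trip through JSON", {
  sc <- barn_scenario(list(zone_config("barn", 5000, 21000, nh3_source = 233,
                                       co2_source = 72000)),
                      climate_config(mean_temp = 17, diurnal_amplitude = 0),
                      event_schedule(c("07:15", "16:30")),
                      herd = herd_config(140, 650, 37),
                      duration_days = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  rt <- read_scenario(path)
  expect_equal(rt$zones[[1]], sc$zones[[1]])
  expect_equal(rt$climate$mean_temp, 17)
  expect_equal(rt$events$event_hours, sc$events$event_hours)
  expect_equal(rt$herd$n_animals, 140)
  expect_equal(rt$duration_days, 2)
  expect_equal(rt$seed, 11)
})

test_that("ground-truth CSV export writes one file per zone plus a parameter sidecar", {
  z <- zone_config("z", 1000, 5000, nh3_source = 10)
  tr <- make_truth(z, duration_days = 1, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_truth_csv(tr, dir)
  expect_true(all(file.exists(paths)))
  expect_true(any(grepl("ground_truth_params.json", paths)))
  lines <- readLines(file.path(dir, "truth_z.csv"), n = 2)
  expect_match(lines[1], "^# units:")
  df <- utils::read.csv(file.path(dir, "truth_z.csv"), comment.char = "#")
  expect_equal(nrow(df), 8640)
  expect_match(df$timestamp[1], "^2023-06-01T00:00:00Z$")
  side <- jsonlite::read_json(file.path(dir, "ground_truth_params.json"))
  expect_equal(side$seed, 5)
})
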