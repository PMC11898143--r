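mk_msg <- function(node, ws) list(node_id = node, window_start = ws)

test_that("messages buffered during an outage are delivered with origin timestamps", {
  st <- gateway_state()
  st <- gateway_step(st, "link_down")
  for (i in 1:5) st <- gateway_step(st, "receive", mk_msg(1L, (i - 1) * 600))
  expect_length(delivered_messages(st), 0)
  st <- gateway_step(st, "link_up")
  got <- delivered_messages(st)
  expect_length(got, 5)
  expect_equal(vapply(got, `[[`, numeric(1), "window_start"), (0:4) * 600)
})

test_that("messages spilled to flash survive a power cycle", {
  st <- gateway_state(ram_capacity = 1)
  st <- gateway_step(st, "receive", mk_msg(1L, 0))      # stays in RAM
  st <- gateway_step(st, "receive", mk_msg(1L, 600))    # pushes first to flash
  st <- gateway_step(st, "power_cycle")                 # RAM content lost
  st <- gateway_step(st, "link_up")
  got <- delivered_messages(st)
  expect_length(got, 1)
  expect_equal(got[[1]]$window_start, 0)                # the spilled message
})

test_that("duplicate packets are delivered exactly once", {
  st <- gateway_state()
  st <- gateway_step(st, "link_up")
  st <- gateway_step(st, "receive", mk_msg(1L, 0))
  st <- gateway_step(st, "receive", mk_msg(1L, 0))
  st <- gateway_step(st, "receive", mk_msg(2L, 0))      # different node: kept
  expect_length(delivered_messages(st), 2)
  # duplicate arriving during an outage is also dropped
  st <- gateway_step(st, "link_down")
  st <- gateway_step(st, "receive", mk_msg(3L, 0))
  st <- gateway_step(st, "receive", mk_msg(3L, 0))
  st <- gateway_step(st, "link_up")
  expect_length(delivered_messages(st), 3)
})

test_that("every unique message is delivered exactly once under random link churn", {
  set.seed(55)
  for (rep in 1:20) {
    st <- gateway_state(ram_capacity = 3)
    sent <- character(0)
    n_msg <- 0
    for (step in 1:60) {
      ev <- sample(c("receive", "link_up", "link_down"), 1,
                   prob = c(0.6, 0.2, 0.2))
      if (ev == "receive") {
        node <- sample(1:3, 1)
        ws <- 600 * sample(0:9, 1)
        sent <- union(sent, paste(node, ws, sep = "/"))
        st <- gateway_step(st, "receive", mk_msg(node, ws))
      } else st <- gateway_step(st, ev)
    }
    st <- gateway_step(st, "link_up")
    keys <- vapply(delivered_messages(st),
                   function(m) paste(m$node_id, m$window_start, sep = "/"),
                   character(1))
    expect_equal(sort(keys), sort(sent))
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("hourly resampling averages available packets and applies the coverage rule", {
  ser <- structure(data.frame(node_id = 1L, timestamp = seq(0, 3000, 600),
                              channel = "nh3", value = 2.0, coverage = 1),
                   resolution = 600, class = c("device_series", "data.frame"))
  h <- resample_series(ser, "hourly")
  expect_equal(h$value, 2.0)
  expect_equal(h$coverage, 1.0)
  sparse <- ser[1:2, ]
  sparse$value <- c(1.0, 3.0)
  attr(sparse, "resolution") <- 600
  h2 <- resample_series(sparse, "hourly")
  expect_true(is.na(h2$value))                 # coverage 1/3 < 0.5
  expect_equal(h2$coverage, 1 / 3)
})

test_that("daily resampling of full hourly coverage is the plain mean", {
  ser <- structure(data.frame(node_id = 1L, timestamp = (0:23) * 3600,
                              channel = "co2", value = 1:24, coverage = 1),
                   resolution = 3600, class = c("device_series", "data.frame"))
  d <- resample_series(ser, "daily")
  expect_equal(d$value, 12.5)
  expect_error(resample_series(d, "hourly"),
               class = "barnsense_resolution_error")
  expect_error(resample_series(ser, "hourly"),
               class = "barnsense_resolution_error")
})

test_that("resampling conserves means under full coverage across resolutions", {
  tr <- dairy_truth(seed = 21)
  pol <- gas_policies()
  s <- simulate_node(tr, "barn", policies = pol, noise_seed = 2, noise = TRUE)
  ten <- packets_to_series(aggregate_packets(s, pol))
  hourly <- resample_series(ten, "hourly")
  daily <- resample_series(hourly, "daily")
  for (ch in c("nh3", "co2", "temp")) {
    m10 <- mean(ten$value[ten$channel == ch])
    mh <- mean(hourly$value[hourly$channel == ch])
    md <- daily$value[daily$channel == ch]
    expect_equal(mh, m10, tolerance = 1e-12)
    expect_equal(md, m10, tolerance = 1e-12)
  }
})

test_that("THI matches its defining formula and boundary behaviour", {
  expect_equal(compute_thi(25, 50), 71.775)
  t0 <- 26 / 1.8                              # 1.8 T - 26 = 0
  for (rh in c(0, 37, 100)) expect_equal(compute_thi(t0, rh), 58.0)
  expect_equal(compute_thi(30, 100), 1.8 * 30 + 32)
  expect_error(compute_thi(25, 101), class = "barnsense_domain_error")
  expect_error(compute_thi(25, -1), class = "barnsense_domain_error")
})

test_that("THI increases with temperature, and with humidity when warm", {
  t <- seq(-5, 40, by = 0.5)
  for (rh in c(0, 50, 99))
    expect_true(all(diff(compute_thi(t, rh)) > 0))
  for (temp in c(15, 25, 35))
    expect_true(all(diff(compute_thi(temp, seq(0, 100, 5))) > 0))
})

test_that("trailing rolling aggregates are right-aligned and fill only when complete", {
  ser <- structure(data.frame(node_id = 1L, timestamp = (0:47) * 3600,
                              channel = "co2", value = 1:48, coverage = 1),
                   resolution = 3600, class = c("device_series", "data.frame"))
  r <- rolling_aggregate(ser, 24, "mean")
  expect_true(all(is.na(r$value[1:23])))
  expect_equal(r$value[24], 12.5)             # mean of hours 1..24
  expect_equal(r$value[48], 36.5)
  cst <- ser; cst$value <- rep(7, 48); attr(cst, "resolution") <- 3600
  expect_equal(rolling_aggregate(cst, 6, "mean")$value[6:48], rep(7, 43))
  spike <- ser; spike$value <- c(rep(0, 9), 50, rep(0, 38))
  attr(spike, "resolution") <- 3600
  rmax <- rolling_aggregate(spike, 6, "max")
  expect_true(all(rmax$value[10:15] == 50))   # spike dominates while in window
  expect_true(all(rmax$value[16:48] == 0))
})

test_that("device-series CSV round-trips with ISO-8601 timestamps", {
  ser <- structure(data.frame(node_id = 1L, timestamp = c(0, 600),
                              channel = "nh3", value = c(1.5, 2.5),
                              coverage = 1),
                   resolution = 600, class = c("device_series", "data.frame"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ser, path)
  txt <- readLines(path, n = 2)
  expect_match(txt[2], "1970-01-01T00:00:00Z")
  rt <- read_series_csv(path, resolution = 600)
  expect_equal(rt$timestamp, ser$timestamp)
  expect_equal(rt$value, ser$value)
})
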