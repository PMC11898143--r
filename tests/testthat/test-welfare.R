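table3_nh3_means <- function() {
  data.frame(node_id = paste0("ID", 1:6), channel = "nh3",
             value = c(7.3, 6.5, 9.5, 11.4, 7.9, 10.4))
}

test_that("threshold assessment flags the devices whose period mean exceeds the limit", {
  rep <- assess_thresholds(table3_nh3_means())
  expect_equal(sum(rep$exceeds), 2)
  expect_equal(sort(rep$node_id[rep$exceeds]), c("ID4", "ID6"))
  zero <- data.frame(node_id = "a", channel = "nh3",
                     timestamp = (0:9) * 600, value = 0)
  r0 <- assess_thresholds(zero)
  expect_false(any(r0$exceeds))
  expect_equal(r0$frac_above, 0)
  # sitting exactly at the limit is not a violation (strict inequality)
  at <- data.frame(node_id = "a", channel = "nh3", value = rep(10, 5))
  expect_false(assess_thresholds(at)$exceeds)
})

test_that("channels without a limit are skipped with a warning", {
  s <- rbind(table3_nh3_means(),
             data.frame(node_id = "ID1", channel = "temp", value = 21.9))
  expect_warning(rep <- assess_thresholds(s), "temp")
  expect_false("temp" %in% rep$channel)
})

test_that("exceedance fraction is monotone under pointwise increase", {
  set.seed(8)
  v <- runif(200, 5, 15)
  s1 <- data.frame(node_id = "a", channel = "nh3", value = v)
  s2 <- s1; s2$value <- s2$value + runif(200, 0, 2)
  f1 <- assess_thresholds(s1)$frac_above
  f2 <- assess_thresholds(s2)$frac_above
  expect_gte(f2, f1)
})

test_that("identical devices share one letter with adjusted p of 1", {
  set.seed(3)
  v <- rnorm(30)
  h <- data.frame(node_id = rep(c("a", "b"), each = 30), value = c(v, v))
  u <- uniformity_test(h)
  expect_equal(unname(u$letters["a"]), unname(u$letters["b"]))
  expect_equal(u$pairs$p_adj, 1, tolerance = 1e-12)
})

test_that("well-separated devices receive different letters", {
  set.seed(9)
  h <- data.frame(node_id = rep(c("a", "b"), each = 100),
                  value = c(rnorm(100, 0, 1), rnorm(100, 5, 1)))  # 5 SD apart
  u <- uniformity_test(h, alpha = 0.01)
  expect_false(u$letters[["a"]] == u$letters[["b"]])
  expect_lt(u$p_value, 0.01)
})

test_that("compact letters are consistent with the pairwise decisions", {
  set.seed(12)
  h <- data.frame(node_id = rep(paste0("d", 1:5), each = 40),
                  value = rnorm(200, rep(c(0, 0.2, 1.5, 1.6, 4), each = 40)))
  u <- uniformity_test(h, alpha = 0.01)
  share <- function(a, b) {
    la <- strsplit(u$letters[[a]], "")[[1]]
    lb <- strsplit(u$letters[[b]], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (i in seq_len(nrow(u$pairs))) {
    p <- u$pairs[i, ]
    if (p$p_adj < u$alpha) expect_false(share(p$a, p$b))
    else expect_true(share(p$a, p$b))
  }
})

test_that("uniformity test rejects insufficient replication", {
  expect_error(uniformity_test(data.frame(node_id = "a", value = 1:5)),
               class = "barnsense_insufficient_data")
  h <- data.frame(node_id = rep(c("a", "b"), c(5, 2)), value = rnorm(7))
  expect_error(uniformity_test(h), class = "barnsense_insufficient_data")
})

test_that("diurnal profiles have zero SE for day-periodic signals", {
  ts <- seq(0, 2 * 86400 - 600, 600)
  cst <- structure(data.frame(node_id = 1L, timestamp = ts, channel = "co2",
                              value = 3.3, coverage = 1),
                   resolution = 600, class = c("device_series", "data.frame"))
  p <- diurnal_profile(cst)
  expect_equal(p$mean, rep(3.3, 24))
  expect_equal(p$se, rep(0, 24))
  sinu <- cst
  sinu$value <- sin(2 * pi * ts / 86400)
  attr(sinu, "resolution") <- 600
  ps <- diurnal_profile(sinu)
  expect_equal(ps$se, rep(0, 24), tolerance = 1e-12)
  expect_equal(which.max(ps$mean) - 1, 6)   # sine peaks at 06:00
  one_day <- cst[1:144, ]
  expect_error(diurnal_profile(one_day), class = "barnsense_insufficient_data")
})

test_that("feeding pulses dominate the diurnal gas profile at the feed hours", {
  z <- zone_config("pen", 400, 8000, nh3_source = 60, co2_source = 4000)
  tr <- make_truth(z, climate_config(diurnal_amplitude = 0, rh_noise_sd = 0),
                   event_schedule(c("07:15", "16:30"), 2, 60),
                   duration_days = 2, seed = 6, init = "steady")
  pol <- gas_policies()
  s <- simulate_node(tr, "pen", policies = pol, noise = FALSE)
  ser <- packets_to_series(aggregate_packets(s, pol))
  prof <- diurnal_profile(ser)
  nh3 <- prof[prof$channel == "nh3", ]
  ranked <- nh3$hour[order(-nh3$mean)]
  expect_equal(ranked[1], 7)                   # morning feed peak
  expect_true(all(ranked[2:3] %in% c(8, 16, 17)))  # afternoon feed + decay tails
  quiet <- nh3$mean[nh3$hour %in% 1:5]
  expect_gt(nh3$mean[nh3$hour == 16], max(quiet))
})

test_that("correlation handles exact linear relations and degenerate input", {
  a <- c(1, 3, 4, 7, 9, 12)
  expect_equal(correlate(a, 2 * a + 1)$r, 1)
  expect_equal(correlate(a, -a)$r, -1)
  expect_error(correlate(a, rep(5, 6)),
               class = "barnsense_undefined_correlation")
  expect_error(correlate(1:2, 2:3), class = "barnsense_insufficient_data")
  set.seed(10)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.5)
  ct <- correlate(x, y)
  expect_equal(ct$r, cor(x, y))
  expect_equal(ct$p_value, cor.test(x, y)$p.value)
})

test_that("IDW maps interpolate exactly at devices and stay within data bounds", {
  pos <- data.frame(node_id = c("a", "b", "c", "d"),
                    x = c(0, 10, 0, 10), y = c(0, 0, 6, 6))
  v <- c(a = 4, b = 4, c = 4, d = 4)
  m <- spatial_map(pos, v, grid_step = 1)
  expect_true(all(abs(m$grid$value - 4) < 1e-12))
  v2 <- c(a = 2, b = 8, c = 5, d = 7)
  m2 <- spatial_map(pos, v2, grid_step = 1)
  expect_true(all(m2$grid$value >= 2 - 1e-12 & m2$grid$value <= 8 + 1e-12))
  for (i in 1:4) {
    at <- m2$grid$value[m2$grid$x == pos$x[i] & m2$grid$y == pos$y[i]]
    expect_equal(at, unname(v2[pos$node_id[i]]))
  }
  # centre of the rectangle is equidistant from all four devices -> plain mean
  centre <- m2$grid$value[m2$grid$x == 5 & m2$grid$y == 3]
  expect_equal(centre, mean(v2))
  expect_error(spatial_map(pos[1:2, ], v2), class = "barnsense_config_error")
  dup <- pos; dup$x[2] <- 0; dup$y[2] <- 0
  expect_error(spatial_map(dup, v2), class = "barnsense_config_error")
})

test_that("the rabbit-house map peaks nearest the hottest device", {
  # six devices in a 12 m x 30 m room, means as recorded by the devices
  pos <- data.frame(node_id = paste0("ID", 1:6),
                    x = c(3, 9, 3, 9, 3, 9), y = c(5, 10, 15, 20, 25, 28))
  means <- c(ID1 = 7.3, ID2 = 6.5, ID3 = 9.5, ID4 = 11.4, ID5 = 7.9,
             ID6 = 10.4)
  m <- spatial_map(pos, means, grid_step = 0.5)
  top <- m$grid[which.max(m$grid$value), ]
  d <- sqrt((pos$x - top$x)^2 + (pos$y - top$y)^2)
  expect_equal(pos$node_id[which.min(d)], "ID4")
  expect_lte(max(m$grid$value), 11.4)
})
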