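#' Welfare air-quality limits
#'
#' Upper limits for gas concentrations in livestock housing, following EFSA
#' guidance: air quality is considered inadequate when NH3 exceeds 10 ppm,
#' CO2 3000 ppm, H2S 0.5 ppm or CO 10 ppm. The same NH3 limit of 10 ppm is
#' used in rabbit welfare guidance. Limits are per-channel and can be
#' overridden per species or site.
#'
#' @param nh3,co2,h2s,co Channel limits in ppm (> 0). The CO entry applies
#'   only if a CO channel is present in the data.
#' @param ... Further named per-channel overrides.
#' @return Named numeric vector of limits.
#' @export
welfare_limits <- function(nh3 = 10, co2 = 3000, h2s = 0.5, co = 10, ...) {
  lim <- c(nh3 = nh3, co2 = co2, h2s = h2s, co = co, ...)
  if (any(lim <= 0))
    stop_barnsense("limits must be positive", "barnsense_config_error")
  lim
}

#' Threshold exceedance assessment
#'
#' Compares each device's record against welfare limits: the period mean
#' concentration (flagged when strictly above the limit -- equality at the
#' boundary is not a violation) and the fraction of time spent above the
#' limit, computed from the finest resolution supplied.
#'
#' @param series Data frame with columns `node_id`, `channel`, `value`
#'   (a `device_series` or any long table of readings; a single row per
#'   device gives a period-mean-only assessment).
#' @param limits Named limit vector from [welfare_limits()]. Channels in the
#'   data without a limit are skipped with a warning.
#' @return A data frame of class `exceedance_report`: per `node_id` and
#'   `channel`, the period `mean`, `frac_above`, the `limit` and the flag
#'   `exceeds` (`mean > limit`).
#' @examples
#' means <- data.frame(node_id = paste0("ID", 1:6), channel = "nh3",
#'                     value = c(7.3, 6.5, 9.5, 11.4, 7.9, 10.4))
#' assess_thresholds(means)   # flags ID4 and ID6
#' @export
assess_thresholds <- function(series, limits = welfare_limits()) {
  if (!nrow(series))
    stop_barnsense("series is empty", "barnsense_config_error")
  chans <- unique(series$channel)
  no_limit <- setdiff(chans, names(limits))
  if (length(no_limit))
    warning(sprintf("no welfare limit for channel(s) %s; skipped",
                    paste(no_limit, collapse = ", ")), call. = FALSE)
  keep <- series$channel %in% names(limits) & !is.na(series$value)
  s <- series[keep, , drop = FALSE]
  if (!nrow(s))
    stop_barnsense("no channels with limits present", "barnsense_config_error")
  parts <- split(s, list(s$node_id, s$channel), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) {
    lim <- limits[[g$channel[1]]]
    data.frame(node_id = g$node_id[1], channel = g$channel[1],
               mean = mean(g$value), frac_above = mean(g$value > lim),
               limit = lim, exceeds = mean(g$value) > lim,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$channel, out$node_id), ]
  rownames(out) <- NULL
  class(out) <- c("exceedance_report", class(out))
  out
}

#' Between-device uniformity test with compact letter display
#'
#' Tests whether monitoring points across a building record the same level
#' of an environmental factor: a one-way analysis of variance on hourly
#' values across devices, followed by Tukey all-pairs comparisons with
#' familywise adjustment, summarized as a compact letter display (devices
#' sharing a letter do not differ at the stated alpha).
#'
#' @param hourly Data frame with columns `node_id` and `value` (hourly
#'   values per device), or a named list of numeric vectors.
#' @param alpha Familywise significance level (default 0.01).
#' @return An object of class `uniformity_result`: per-device `means`,
#'   `pairs` (device pair, mean difference, Tukey-adjusted p), `letters`
#'   (compact letter display, letters ordered by descending mean),
#'   `statistic` (overall F), `p_value` and `alpha`.
#' @export
uniformity_test <- function(hourly, alpha = 0.01) {
  if (is.list(hourly) && !is.data.frame(hourly))
    hourly <- data.frame(
      node_id = rep(names(hourly), lengths(hourly)),
      value = unlist(hourly, use.names = FALSE))
  hourly <- hourly[!is.na(hourly$value), , drop = FALSE]
  counts <- table(hourly$node_id)
  if (length(counts) < 2L)
    stop_barnsense("need at least two devices", "barnsense_insufficient_data")
  if (any(counts < 3L))
    stop_barnsense("need at least three hourly values per device",
                   "barnsense_insufficient_data")
  hourly$node_id <- factor(hourly$node_id)
  fit <- stats::aov(value ~ node_id, data = hourly)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$node_id
  pairs <- data.frame(a = sub("-.*", "", rownames(tuk)),
                      b = sub(".*-", "", rownames(tuk)),
                      diff = tuk[, "diff"], p_adj = tuk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  means <- tapply(hourly$value, hourly$node_id, mean)
  letters <- compact_letters(names(means), pairs, means, alpha)
  structure(list(means = means, pairs = pairs, letters = letters,
                 statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 alpha = alpha),
            class = "uniformity_result")
}

# Insert-and-absorb compact letter display. Devices sharing a letter have no
# significant pairwise difference at alpha.
compact_letters <- function(devices, pairs, means, alpha) {
  sets <- list(devices)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$a[i]; b <- sig$b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop any set contained in another
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && keep[j] && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]]) &&
          !(all(new_sets[[k]] %in% new_sets[[j]]) && j < k))
        keep[j] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  sets <- Filter(length, sets)
  # order letters by the best (highest-mean) device they contain
  ord <- order(vapply(sets, function(s) -max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- vapply(devices, function(d) {
    paste(letters[which(vapply(sets, function(s) d %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("Device uniformity (one-way ANOVA F = %.2f, p = %.3g, alpha = %g)\n",
              x$statistic, x$p_value, x$alpha))
  df <- data.frame(device = names(x$means), mean = round(as.numeric(x$means), 3),
                   group = x$letters[names(x$means)])
  print(df[order(-df$mean), ], row.names = FALSE)
  invisible(x)
}

#' Diurnal (hour-of-day) profile
#'
#' Average daily pattern of a series: for every hour of day, the mean across
#' days and its standard error (SE over day-level hourly means). Reveals
#' management-driven concentration peaks such as the morning and afternoon
#' feed deliveries.
#'
#' @param series A `device_series` at 10-min or hourly resolution with at
#'   least two full days of data.
#' @return Data frame: `channel`, `hour` (0-23), `mean`, `se`, `n_days`.
#' @export
diurnal_profile <- function(series) {
  day <- floor(series$timestamp / 86400)
  if (length(unique(day)) < 2L)
    stop_barnsense("diurnal SE needs at least two days of data",
                   "barnsense_insufficient_data")
  hour <- floor((series$timestamp %% 86400) / 3600)
  ok <- !is.na(series$value)
  key <- paste(series$channel, day, hour, sep = "\r")
  daily <- tapply(series$value[ok], key[ok], mean)
  parts <- do.call(rbind, strsplit(names(daily), "\r", fixed = TRUE))
  dh <- data.frame(channel = parts[, 1], hour = as.integer(parts[, 3]),
                   value = as.numeric(daily), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(dh, list(dh$channel, dh$hour), drop = TRUE),
                               function(g) {
    n <- nrow(g)
    data.frame(channel = g$channel[1], hour = g$hour[1], mean = mean(g$value),
               se = if (n > 1) stats::sd(g$value) / sqrt(n) else NA_real_,
               n_days = n, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$channel, out$hour), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two daily series
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform, for paired daily values (such as temperature vs CO2).
#'
#' @param a,b Paired numeric vectors (at least 3 complete pairs, non-zero
#'   variance).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop_barnsense("need at least three paired values",
                   "barnsense_insufficient_data")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_barnsense("correlation undefined for zero-variance input",
                   "barnsense_undefined_correlation")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' Inverse-distance-weighted spatial concentration map
#'
#' Interpolates per-device period means onto a regular grid with
#' inverse-distance weighting, producing a concentration distribution map of
#' the building. The field equals each device's value at its position and is
#' always bounded by the minimum and maximum device means (IDW weights are
#' convex).
#'
#' @param positions Data frame `node_id, x, y` in metres, distinct positions,
#'   at least 3 devices.
#' @param means Named numeric vector of per-device values (names matching
#'   `node_id`).
#' @param grid_step Grid resolution in metres (default 0.5).
#' @param power IDW exponent (default 2).
#' @return An object of class `spatial_map`: list with `grid`
#'   (`x, y, value`), `positions`, `means`, `power`, `grid_step`.
#' @export
spatial_map <- function(positions, means, grid_step = 0.5, power = 2) {
  if (nrow(positions) < 3L)
    stop_barnsense("need at least three devices", "barnsense_config_error")
  if (anyDuplicated(positions[, c("x", "y")]))
    stop_barnsense("device positions must be distinct",
                   "barnsense_config_error")
  v <- means[as.character(positions$node_id)]
  if (any(is.na(v)))
    stop_barnsense("means must cover every positioned device",
                   "barnsense_config_error")
  gx <- seq(min(positions$x), max(positions$x), by = grid_step)
  gy <- seq(min(positions$y), max(positions$y), by = grid_step)
  grid <- expand.grid(x = gx, y = gy)
  d2 <- outer(grid$x, positions$x, `-`)^2 + outer(grid$y, positions$y, `-`)^2
  d <- sqrt(d2)
  w <- 1 / d^power
  at_dev <- d < 1e-9
  hit <- rowSums(at_dev) > 0
  w[hit, ] <- at_dev[hit, ]        # exact at device positions
  grid$value <- as.numeric((w %*% v) / rowSums(w))
  structure(list(grid = grid, positions = positions, means = v,
                 power = power, grid_step = grid_step),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("IDW map: %d devices, %d grid points (step %g m, power %g)\n",
              nrow(x$positions), nrow(x$grid), x$grid_step, x$power))
  cat(sprintf("  field range: [%.3g, %.3g]\n", min(x$grid$value),
              max(x$grid$value)))
  invisible(x)
}

#' @export
print.exceedance_report <- function(x, ...) {
  cat("Welfare threshold assessment\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, 3)
  df$frac_above <- round(df$frac_above, 3)
  print(df, row.names = FALSE)
  n <- sum(x$exceeds)
  cat(sprintf("%d device-channel(s) with period mean above the limit\n", n))
  invisible(x)
}
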