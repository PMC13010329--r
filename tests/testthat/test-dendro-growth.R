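# Dendrometer processing: displacement -> basal area, the zero-growth
# decomposition against a brute-force oracle, diurnal partitioning, and
# Huber-value tracking.

trees1 <- data.frame(tree_id = "t1", treatment = "control",
                     leaf_area_m2 = 0.0981, initial_diameter_mm = 10)

test_that("displacement converts to diameter and circular basal area", {
  d <- data.frame(timestamp = as.POSIXct("2023-06-06", tz = "UTC") + 0:2 * 3600,
                  tree_id = "t1", displacement_um = c(0, 1000, 1000))
  ba <- to_basal_area(d, trees1)
  expect_equal(ba$basal_area_mm2[1], pi * 100 / 4)
  expect_equal(ba$basal_area_mm2[1], 78.5398, tolerance = 1e-5)
  expect_equal(ba$diameter_mm[2], 11)
  expect_equal(ba$basal_area_mm2[2], pi * 121 / 4)
  expect_equal(ba$basal_area_mm2[2], 95.0332, tolerance = 1e-5)
  # constant trace -> constant area
  expect_equal(ba$basal_area_mm2[2], ba$basal_area_mm2[3])
  bad <- d
  bad$displacement_um <- -2e4
  expect_error(to_basal_area(bad, trees1), "non-positive diameter")
})

test_that("zero-growth attributes growth only to new stem-size maxima", {
  diam <- c(10.0, 10.1, 10.05, 10.2)
  ba <- make_ba_df(pi * diam^2 / 4)
  g <- zero_growth(ba)
  expect_equal(g$growth_cum_mm2[4], pi / 4 * (10.2^2 - 10^2))
  # growth occurs only at steps 2 and 4
  expect_true(all(g$growth_increment_mm2[c(2, 4)] > 0))
  expect_equal(g$growth_increment_mm2[3], 0)
  # shrink step builds tree water deficit instead
  expect_gt(g$twd_mm2[3], 0)
  expect_equal(g$twd_mm2[c(1, 2, 4)], c(0, 0, 0))

  shrink <- make_ba_df(seq(80, 70, length.out = 10))
  gs <- zero_growth(shrink)
  expect_true(all(gs$growth_cum_mm2 == 0))
  expect_true(all(gs$twd_mm2[-1] > 0))

  grow <- make_ba_df(seq(80, 90, length.out = 10))
  gg <- zero_growth(grow)
  expect_equal(gg$growth_cum_mm2, seq(0, 10, length.out = 10))
  expect_true(all(gg$twd_mm2 == 0))

  unsorted <- ba[c(2, 1, 3, 4), ]
  expect_error(zero_growth(unsorted), "strictly increasing")
})

test_that("zero-growth matches the explicit-loop oracle on random traces", {
  set.seed(123)
  for (i in 1:30) {
    kind <- i %% 3
    n <- 2000
    ba <- switch(kind + 1,
                 80 + cumsum(abs(rnorm(n, 0.01, 0.02))),        # monotone up
                 80 - cumsum(abs(rnorm(n, 0.005, 0.01))) * 0.1, # shrink only
                 80 + cumsum(rnorm(n, 0.002, 0.05)))            # shrink-swell
    g <- zero_growth(make_ba_df(ba))
    oracle <- zero_growth_oracle(ba)
    expect_identical(g$growth_cum_mm2, oracle$growth_cum)
    expect_identical(g$twd_mm2, oracle$twd)
    # structural invariants
    expect_true(all(diff(g$growth_cum_mm2) >= 0))
    expect_true(all(g$twd_mm2 >= 0))
    expect_equal(g$growth_cum_mm2 - g$twd_mm2, ba - ba[1])
  }
})

test_that("daily growth sums increments per day", {
  # one step jump of 1 mm2 on the second day
  ts <- as.POSIXct("2023-06-06 00:00:00", tz = "UTC") + (0:71) * 3600
  ba <- rep(80, 72)
  ba[30:72] <- 81
  dg <- daily_growth(zero_growth(data.frame(timestamp = ts, tree_id = "t1",
                                            basal_area_mm2 = ba)))
  expect_equal(dg$growth_mm2, c(0, 1, 0))

  # diurnal shrink-swell below the running max registers no growth
  h <- hour_of_day(ts)
  ba2 <- 80 - 0.2 * pmax(0, sin(pi * (h - 6) / 14)) * (h >= 6 & h < 20)
  dg2 <- daily_growth(zero_growth(data.frame(timestamp = ts, tree_id = "t1",
                                             basal_area_mm2 = ba2)))
  expect_true(all(dg2$growth_mm2 == 0))
})

test_that("the first recovery day is masked from reported growth", {
  dg <- data.frame(tree_id = "t1", date = as.Date("2023-07-04") + -1:2,
                   growth_mm2 = c(0.1, 0.9, 0.2, 0.3))
  out <- recovery_mask(dg, as.Date("2023-07-04"))
  expect_true(is.na(out$growth_mm2[out$date == as.Date("2023-07-04")]))
  expect_true(out$masked[2])
  expect_equal(out$growth_mm2[-2], dg$growth_mm2[-2])
})

test_that("diurnal partition recovers window shares and rates", {
  ts <- as.POSIXct("2023-06-06 00:00:00", tz = "UTC") + (0:(24 * 4 - 1)) * 3600
  h <- hour_of_day(ts)

  # uniform growth across all 24 h: daytime fraction exactly 12/24
  ba_u <- 80 + seq_along(ts) * 0.01
  p_u <- diurnal_partition(zero_growth(data.frame(
    timestamp = ts, tree_id = "t1", basal_area_mm2 = ba_u)))
  expect_equal(p_u$daytime_fraction, 0.5, tolerance = 1e-12)
  expect_equal(p_u$daytime_rate, 0.01, tolerance = 1e-12)
  expect_equal(p_u$nighttime_rate, 0.01, tolerance = 1e-12)

  # growth confined to 00:00-05:00: daytime rate zero
  inc <- ifelse(h < 5, 0.02, 0)
  ba_n <- 80 + cumsum(inc)
  # shift increments: increment over (t_i, t_i+1] uses start-hour attribution
  ba_n <- c(80, 80 + cumsum(inc[-length(inc)]))
  p_n <- diurnal_partition(zero_growth(data.frame(
    timestamp = ts, tree_id = "t1", basal_area_mm2 = ba_n)))
  expect_equal(p_n$daytime_rate, 0, tolerance = 1e-12)
  expect_equal(p_n$daytime_fraction, 0, tolerance = 1e-12)
  expect_gt(p_n$nighttime_rate, 0)
})

test_that("a generator fixture with 30 percent daytime growth is recovered", {
  # equal drought/recovery rates keep every day's hourly increment pattern
  # identical, so the composite recovers the injected share exactly
  cfg <- tiny_config(daytime_growth_fraction = c(control = 0.30),
                     diurnal_shrink_um = c(control = 0, mild = 0, severe = 0),
                     growth_drought = c(control = 0.58),
                     growth_recovery = c(control = 0.58),
                     drought_days = 6L, recovery_days = 6L)
  ds <- generate_scenario(cfg)
  g <- zero_growth(to_basal_area(ds$dendro, ds$trees))
  p <- diurnal_partition(g, window = c(5, 17))
  expect_equal(p$daytime_fraction, 0.30, tolerance = 1e-9)
  # partition completeness: day + night shares sum to 1
  comp <- p$composite
  is_day <- comp$hour >= 5 & comp$hour < 17
  expect_equal(sum(comp$mean_increment_mm2[is_day]) +
                 sum(comp$mean_increment_mm2[!is_day]),
               sum(comp$mean_increment_mm2))
})

test_that("Huber value scales basal area by leaf area and never decreases", {
  d <- data.frame(timestamp = as.POSIXct("2023-06-06", tz = "UTC") + 0:9 * 3600,
                  tree_id = "t1", displacement_um = 0)
  ba <- to_basal_area(d, trees1)
  hv <- huber_series(ba, trees1)
  expect_equal(hv$hv_mm2_cm2[1], (pi * 100 / 4) / 981)
  expect_equal(hv$hv_mm2_cm2[1], 0.080, tolerance = 1e-2)

  trees2 <- trees1
  trees2$leaf_area_m2 <- 2 * trees1$leaf_area_m2
  hv2 <- huber_series(ba, trees2)
  expect_equal(hv2$hv_mm2_cm2, hv$hv_mm2_cm2 / 2)

  # shrinking stem under the running-max rule: constant, never decreasing
  d3 <- d
  d3$displacement_um <- seq(0, -500, length.out = 10)
  hv3 <- huber_series(to_basal_area(d3, trees1), trees1)
  expect_true(all(diff(hv3$hv_mm2_cm2) == 0))
  hv3i <- huber_series(to_basal_area(d3, trees1), trees1, "instantaneous")
  expect_true(all(diff(hv3i$hv_mm2_cm2) < 0))
})

test_that("start-of-day Huber sampling picks the configured hour with tolerance", {
  ts <- as.POSIXct("2023-06-06 00:00:00", tz = "UTC") + (0:47) * 3600
  hv <- data.frame(timestamp = ts, tree_id = "t1",
                   hv_mm2_cm2 = 0.08)
  sod <- start_of_day_hv(hv, hour = 5)
  expect_equal(sod$hv_mm2_cm2, c(0.08, 0.08))

  # step increase at noon: the day reports the pre-noon value
  hv2 <- hv
  hv2$hv_mm2_cm2 <- ifelse(hour_of_day(ts) >= 12, 0.1, 0.08)
  expect_equal(start_of_day_hv(hv2, hour = 5)$hv_mm2_cm2[1], 0.08)

  # missing 05:00 sample: nearest within 1 h, else missing
  hv3 <- hv[!(hour_of_day(ts) == 5), ]
  expect_equal(start_of_day_hv(hv3, hour = 5)$hv_mm2_cm2[1], 0.08)
  hv4 <- hv[!(hour_of_day(ts) %in% 4:6), ]
  expect_true(all(is.na(start_of_day_hv(hv4, hour = 5)$hv_mm2_cm2)))
})
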