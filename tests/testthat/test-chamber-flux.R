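# Chamber flux computation: dilution correction, background subtraction,
# the compartment mass balance, and leaf-area normalized derivations.

test_that("water-dilution correction matches hand arithmetic and never shrinks", {
  expect_identical(dry_mole_fraction(440, 0), 440)
  expect_equal(dry_mole_fraction(440, 20), 440 / 0.98)
  expect_identical(dry_mole_fraction(0, 8), 0)
  w <- seq(0, 50, by = 5)
  expect_true(all(dry_mole_fraction(420, w) >= 420))
  expect_error(dry_mole_fraction(440, 1000), "humidity")
  expect_error(dry_mole_fraction(440, -1), "humidity")
})

test_that("blank background subtraction is plain differential arithmetic", {
  expect_identical(background_correct(-10.15, 0.15), -10.30)
  expect_identical(background_correct(5, 0), 5)
  # a zero-flux record seen through a +0.15/+0.03 background
  expect_equal(background_correct(c(0, 0), c(0.15, 0.03)), c(-0.15, -0.03))
})

test_that("compartment CO2 mass balance has the uptake-positive sign convention", {
  expect_identical(compartment_co2_flux(0.01, 450, 450), 0)
  expect_equal(compartment_co2_flux(0.01, 440, 450), 1.0e-7)
  expect_equal(compartment_co2_flux(0.01, 460, 450), -1.0e-7)
  expect_error(compartment_co2_flux(0, 440, 450), "flow")
  expect_error(compartment_co2_flux(-0.01, 440, 450), "flow")
})

test_that("transpiration follows the chamber water balance and leaf-area scaling", {
  expect_identical(transpiration(0.01, 8, 8, 0.005), 0)
  # 0.01 * (0.5e-3 / 0.9915) / 0.005 * 1000
  expect_equal(transpiration(0.01, 8.5, 8.0, 0.005),
               0.01 * (0.5e-3 / (1 - 8.5e-3)) / 0.005 * 1000)
  expect_equal(transpiration(0.01, 8.5, 8.0, 0.005), 1.00857, tolerance = 1e-5)
  expect_equal(transpiration(0.01, 8.5, 8.0, 0.010),
               transpiration(0.01, 8.5, 8.0, 0.005) / 2)
  expect_error(transpiration(0.01, 8.5, 8.0, 0), "leaf_area")
})

test_that("stomatal conductance is E over the mole-fraction deficit", {
  expect_identical(stomatal_conductance(0, 23, 8, 101.3), 0)
  # build air temperature giving exactly VPD = 1.5 kPa at w_sample = 8,
  # P = 101.3 kPa, inverting the Tetens curve independently
  p <- 101.3
  w <- 8
  e_target <- 1.5 + w / 1000 * p
  lr <- log(e_target / 0.6108)
  t_c <- 237.3 * lr / (17.27 - lr)
  expect_equal(stomatal_conductance(1.0, t_c, w, p), 1.0 / (1.5 / p),
               tolerance = 1e-10)
  expect_equal(stomatal_conductance(1.0, t_c, w, p), 67.53, tolerance = 1e-3)
  # halving the deficit doubles conductance
  e_half <- 0.75 + w / 1000 * p
  lr2 <- log(e_half / 0.6108)
  t2 <- 237.3 * lr2 / (17.27 - lr2)
  expect_equal(stomatal_conductance(1.0, t2, w, p),
               2 * stomatal_conductance(1.0, t_c, w, p), tolerance = 1e-10)
  # saturated chamber air masks the point
  expect_true(is.na(stomatal_conductance(1.0, 10, 50, p)))
})

test_that("net assimilation and intrinsic WUE match hand arithmetic", {
  expect_identical(net_assimilation(0, 0.005), 0)
  expect_equal(net_assimilation(3.0e-8, 0.005), 6.0)
  expect_equal(wue_i(6.0, 200), 30)
  expect_true(is.na(wue_i(6.0, 0)))
  # negative under net daytime respiration, not masked
  expect_equal(wue_i(-2, 100), -20)
})

test_that("resampling is idempotent on gridded data and interpolates linearly", {
  ts <- as.POSIXct("2023-06-06 00:00:00", tz = "UTC") + (0:5) * 3600
  x <- data.frame(timestamp = ts, tree_id = "t1", compartment = "shoot",
                  v = c(10, 12, 14, 16, 18, 20))
  out <- resample_cycle(x, 60, 180)
  expect_equal(out$v, x$v)
  expect_equal(out$timestamp, x$timestamp)
  # linear midpoint
  x2 <- data.frame(timestamp = ts[c(1, 3)], tree_id = "t1",
                   compartment = "shoot", v = c(10, 20))
  out2 <- resample_cycle(x2, 60, 180)
  expect_equal(out2$v, c(10, 15, 20))
})

test_that("long gaps are left missing rather than interpolated", {
  ts <- as.POSIXct("2023-06-06 00:00:00", tz = "UTC") + c(0, 1, 6, 7) * 3600
  x <- data.frame(timestamp = ts, tree_id = "t1", compartment = "shoot",
                  v = c(1, 2, 12, 14))
  out <- resample_cycle(x, 60, gap_max_min = 180)
  # the 5-hour gap: interior points masked, endpoints kept
  expect_equal(out$v[out$timestamp %in% ts], c(1, 2, 12, 14))
  interior <- !(out$timestamp %in% ts)
  expect_true(all(is.na(out$v[interior])))
  expect_error(resample_cycle(x[1, ]), "at least 2")
})

test_that("flux computation inverts the noise-free generator to ground truth", {
  ds <- generate_scenario(tiny_config(n_trees = c(control = 1L, severe = 1L)))
  fx <- compute_fluxes(ds$chamber, ds$trees)
  m <- merge(fx, ds$truth$flux, by = c("timestamp", "tree_id", "compartment"),
             suffixes = c("", "_true"))
  expect_equal(nrow(m), nrow(ds$truth$flux))
  rel <- abs(m$f_co2_mol_s - m$f_co2_mol_s_true) /
    pmax(abs(m$f_co2_mol_s_true), 1e-10)
  expect_lt(max(rel), 1e-12)
  sh <- m[m$compartment == "shoot", ]
  rel_e <- abs(sh$e_mmol_m2_s - sh$e_mmol_m2_s_true) /
    pmax(abs(sh$e_mmol_m2_s_true), 1e-10)
  expect_lt(max(rel_e), 1e-12)
})

test_that("computing the mass balance on wet fractions only matches dry when streams are equally moist", {
  c_ref_wet <- 445.6
  w <- 8
  # same humidity in both streams: drying rescales both sides identically
  f_wet <- compartment_co2_flux(0.01, 440.0, c_ref_wet)
  f_dry <- compartment_co2_flux(0.01, dry_mole_fraction(440.0, w),
                                dry_mole_fraction(c_ref_wet, w))
  expect_equal(f_dry, f_wet / (1 - w / 1000))
  # with unequal humidity the orders differ (dilution is not a no-op)
  f_dry2 <- compartment_co2_flux(0.01, dry_mole_fraction(440.0, 10),
                                 dry_mole_fraction(c_ref_wet, 8))
  expect_false(isTRUE(all.equal(f_dry2, f_wet)))
})

test_that("records without a time-matched blank are masked, not zeroed", {
  ts <- as.POSIXct("2023-06-06 12:00:00", tz = "UTC")
  ch <- rbind(
    data.frame(timestamp = ts, tree_id = "t1", compartment = "shoot",
               c_ref_ppm = 445.6, c_sample_ppm = 440, w_ref_mmol = 8,
               w_sample_mmol = 8.2, flow_mol_s = 0.01, t_air_c = 23,
               p_kpa = 101.3, par_umol = 500),
    data.frame(timestamp = ts - 10 * 3600, tree_id = "blank_shoot",
               compartment = "blank", c_ref_ppm = 445.6, c_sample_ppm = 445.75,
               w_ref_mmol = 8, w_sample_mmol = 8.03, flow_mol_s = 0.01,
               t_air_c = 23, p_kpa = 101.3, par_umol = 500))
  trees <- data.frame(tree_id = "t1", leaf_area_m2 = 0.1)
  fx <- compute_fluxes(ch, trees, blank_tolerance_min = 90)
  expect_true(is.na(fx$f_co2_mol_s))
  # and with no blanks at all, a hard error
  expect_error(compute_fluxes(ch[1, ], trees), "blank")
})
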