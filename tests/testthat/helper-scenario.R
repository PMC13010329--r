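# Shared fixtures: small scenario configurations built in code.

quiet_noise <- c(co2_ppm = 0, h2o_mmol = 0, dendro_um = 0, swc_pct = 0)

# A short, noise-free, single-treatment scenario for exactness checks.
tiny_config <- function(..., drought_days = 4L, recovery_days = 4L,
                        n_trees = c(control = 1L)) {
  scenario_config(
    n_trees = n_trees,
    drought_days = drought_days, recovery_days = recovery_days,
    noise = quiet_noise,
    leaf_area_sd = 0, initial_diameter_sd = 0,
    ...
  )
}

# Hourly chamber-style flux table with prescribed constant compartment
# fluxes for one tree and one day.
constant_flux_table <- function(f_shoot, f_root, tree_id = "t1",
                                date = as.Date("2023-06-06"), hours = 0:23) {
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + hours * 3600
  rbind(
    data.frame(timestamp = ts, tree_id = tree_id, compartment = "shoot",
               f_co2_mol_s = f_shoot),
    data.frame(timestamp = ts, tree_id = tree_id, compartment = "root",
               f_co2_mol_s = f_root)
  )
}

# Explicit-loop zero-growth oracle: tracks the maximum one step at a time.
zero_growth_oracle <- function(ba) {
  n <- length(ba)
  growth <- twd <- numeric(n)
  m <- ba[1]
  for (i in seq_len(n)) {
    if (ba[i] > m) m <- ba[i]
    growth[i] <- m - ba[1]
    twd[i] <- m - ba[i]
  }
  list(growth_cum = growth, twd = twd)
}

make_ba_df <- function(ba, tree_id = "t1",
                       start = as.POSIXct("2023-06-06 00:00:00", tz = "UTC"),
                       step_s = 3600) {
  data.frame(timestamp = start + (seq_along(ba) - 1) * step_s,
             tree_id = tree_id, basal_area_mm2 = ba,
             stringsAsFactors = FALSE)
}
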