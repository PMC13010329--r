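# Synthetic drought-recovery scenario generator.
#
# The generator emulates a whole-tree gas flux chamber facility: every tree
# has a shoot and a root chamber continuously supplied with air of fixed CO2
# and H2O content, and the sample (return) airstream is depleted or enriched
# according to the tree's true flux. Two plant-free blank chambers carry the
# small background offsets that real substrate produces. Stem diameter traces
# combine irreversible growth, reversible diurnal shrink-swell, and
# drought-induced elastic contraction. Ground truth (true fluxes, true daily
# growth, true treatment multipliers) is retained alongside the observables
# and is consumed only by validation code, never by the analysis pipeline.

#' Configure a synthetic drought-recovery scenario
#'
#' Builds the parameter set for [generate_scenario()]. Defaults describe a
#' juvenile-conifer greenhouse experiment: 28 days of drought followed by 35
#' days of recovery, hourly sampling, three treatments (well-watered control,
#' mild drought, severe drought) with 6/5/4 chamber trees, a 15-hour
#' photoperiod, and supply air at 445.6 ppm CO2 and 8.0 mmol mol-1 H2O.
#'
#' Drought is imposed as a multiplicative effect trajectory on the whole net
#' compartment flux: a linear ramp from 1 at drought onset to
#' `drought_end_multiplier` at the drought/recovery transition, then a linear
#' ramp to `recovery_end_multiplier` over `recovery_ramp_days`, constant
#' thereafter. A mild seasonal trend (`seasonal_amplitude`) reproduces the
#' steadily rising gas exchange of unstressed trees.
#'
#' @param n_trees named integer vector of trees per treatment; names must be
#'   a subset of `control`, `mild`, `severe`.
#' @param start_date first day of the drought period (`Date` or string).
#' @param drought_days,recovery_days length of the two periods in days.
#' @param sampling_interval chamber sampling interval in minutes; must divide
#'   24 h.
#' @param c_ref_ppm,w_ref_mmol supply-air CO2 (µmol mol-1 moist air) and H2O
#'   (mmol mol-1 moist air).
#' @param flow_mol_s molar air flow through each chamber (mol s-1).
#' @param t_air_c baseline chamber air temperature (deg C).
#' @param p_kpa ambient pressure (kPa).
#' @param par_peak photoperiod-peak photosynthetically active radiation
#'   (µmol m-2 s-1).
#' @param photoperiod start and end hour of the lit period.
#' @param anet_peak light-saturated net assimilation of an unstressed tree
#'   (µmol CO2 m-2 leaf s-1).
#' @param shoot_resp,root_resp dark respiration per unit leaf area
#'   (mol CO2 s-1 m-2 leaf).
#' @param e_peak,e_night peak daytime and constant nighttime transpiration
#'   (mmol H2O m-2 leaf s-1).
#' @param drought_end_multiplier,recovery_end_multiplier named vectors in
#'   \[0, 1\]: flux multiplier reached at the end of drought and at the end of
#'   the post-drought ramp.
#' @param recovery_ramp_days days over which the multiplier relaxes from its
#'   end-of-drought value to `recovery_end_multiplier`.
#' @param seasonal_amplitude relative amplitude of the linear seasonal trend
#'   applied to all fluxes (0.2 means ±20 percent across the experiment, mean 1).
#' @param growth_drought,growth_recovery named vectors of true basal-area
#'   growth rates (mm2 d-1) during drought and recovery.
#' @param growth_resume_delay days after rewatering before growth resumes
#'   (models the post-drought growth lag of severely stressed stems).
#' @param daytime_growth_fraction fraction of each day's growth placed inside
#'   `growth_window`.
#' @param growth_window start/end hour of the daytime growth window.
#' @param diurnal_shrink_um amplitude of reversible diurnal stem shrinkage
#'   (µm diameter) per treatment.
#' @param drought_shrink_um maximum drought-induced elastic stem contraction
#'   (µm diameter) per treatment, proportional to the water-status deficit.
#' @param leaf_area_m2,leaf_area_sd mean and between-tree sd of leaf area.
#' @param initial_diameter_mm,initial_diameter_sd mean and sd of initial
#'   caliper diameter.
#' @param sla_m2_g specific leaf area used to back-compute leaf dry mass.
#' @param root_shoot_ratio named vector of final root:shoot biomass ratios.
#' @param blank_offset constant background offsets carried by every sample
#'   stream and measured by the blank chambers (ppm CO2, mmol mol-1 H2O).
#' @param noise named vector of Gaussian measurement noise sd per channel:
#'   `co2_ppm`, `h2o_mmol`, `dendro_um`, `swc_pct`, `destructive` (relative).
#' @param destructive data frame of treatment-level destructive-sample means
#'   (columns `treatment`, `day`, `psi_md_mpa`, `aba_ng_g`, `sugar_pct_dw`,
#'   `starch_pct_dw`); `NULL` for the built-in default curves.
#' @param n_pilot pilot (destructively sampled) trees per treatment.
#' @param seed integer seed; expanded deterministically into per-stream child
#'   seeds.
#'
#' @return an object of class `scenario_config`.
#' @seealso [generate_scenario()]
#' @export
scenario_config <- function(n_trees = c(control = 6L, mild = 5L, severe = 4L),
                            start_date = "2023-06-06",
                            drought_days = 28L,
                            recovery_days = 35L,
                            sampling_interval = 60,
                            c_ref_ppm = 445.6,
                            w_ref_mmol = 8.0,
                            flow_mol_s = 0.01,
                            t_air_c = 23,
                            p_kpa = 101.3,
                            par_peak = 942,
                            photoperiod = c(5, 20),
                            anet_peak = 6.5,
                            shoot_resp = 3.0e-7,
                            root_resp = 5.8e-7,
                            e_peak = 1.5,
                            e_night = 0.05,
                            drought_end_multiplier = c(control = 1, mild = 0.45, severe = 0.05),
                            recovery_end_multiplier = c(control = 1, mild = 1, severe = 0.5),
                            recovery_ramp_days = 20,
                            seasonal_amplitude = 0.2,
                            growth_drought = c(control = 0.58, mild = 0.28, severe = 0.04),
                            growth_recovery = c(control = 0.80, mild = 0.61, severe = 0.40),
                            growth_resume_delay = c(control = 0, mild = 0, severe = 7),
                            daytime_growth_fraction = c(control = 0.30, mild = 0.10, severe = 0.05),
                            growth_window = c(5, 17),
                            diurnal_shrink_um = c(control = 2, mild = 10, severe = 15),
                            drought_shrink_um = c(control = 0, mild = 20, severe = 120),
                            leaf_area_m2 = 0.10,
                            leaf_area_sd = 0.01,
                            initial_diameter_mm = 10,
                            initial_diameter_sd = 0.8,
                            sla_m2_g = 0.006,
                            root_shoot_ratio = c(control = 0.67, mild = 0.42, severe = 0.37),
                            blank_offset = c(co2_ppm = 0.15, h2o_mmol = 0.03),
                            noise = c(co2_ppm = 0.2, h2o_mmol = 0.02,
                                      dendro_um = 1.5, swc_pct = 0.5),
                            destructive = NULL,
                            n_pilot = 5L,
                            seed = 1L) {
  treatments <- names(n_trees)
  if (is.null(treatments) || !all(treatments %in% c("control", "mild", "severe"))) {
    stop("n_trees must be a named vector with names among 'control', 'mild', 'severe'",
         call. = FALSE)
  }
  if (any(n_trees < 1)) stop("n_trees must be >= 1 per treatment", call. = FALSE)
  if (drought_days < 1 || recovery_days < 1) {
    stop("drought_days and recovery_days must be >= 1", call. = FALSE)
  }
  if (1440 %% sampling_interval != 0) {
    stop("sampling_interval (minutes) must divide 24 h", call. = FALSE)
  }
  for (v in list(drought_end_multiplier, recovery_end_multiplier)) {
    if (any(v < 0 | v > 1)) {
      stop("drought-effect multipliers must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(noise < 0)) stop("noise sd must be >= 0", call. = FALSE)
  if (leaf_area_m2 <= 0) stop("leaf_area_m2 must be > 0", call. = FALSE)
  if (initial_diameter_mm <= 0) stop("initial_diameter_mm must be > 0", call. = FALSE)
  stopifnot(length(photoperiod) == 2, photoperiod[1] < photoperiod[2],
            photoperiod[1] >= 0, photoperiod[2] <= 24,
            length(growth_window) == 2, growth_window[1] < growth_window[2])

  cfg <- list(
    n_trees = n_trees, treatments = treatments,
    start_date = as.character(start_date),
    drought_days = as.integer(drought_days),
    recovery_days = as.integer(recovery_days),
    sampling_interval = sampling_interval,
    c_ref_ppm = c_ref_ppm, w_ref_mmol = w_ref_mmol, flow_mol_s = flow_mol_s,
    t_air_c = t_air_c, p_kpa = p_kpa, par_peak = par_peak,
    photoperiod = photoperiod, anet_peak = anet_peak,
    shoot_resp = shoot_resp, root_resp = root_resp,
    e_peak = e_peak, e_night = e_night,
    drought_end_multiplier = drought_end_multiplier,
    recovery_end_multiplier = recovery_end_multiplier,
    recovery_ramp_days = recovery_ramp_days,
    seasonal_amplitude = seasonal_amplitude,
    growth_drought = growth_drought, growth_recovery = growth_recovery,
    growth_resume_delay = growth_resume_delay,
    daytime_growth_fraction = daytime_growth_fraction,
    growth_window = growth_window,
    diurnal_shrink_um = diurnal_shrink_um,
    drought_shrink_um = drought_shrink_um,
    leaf_area_m2 = leaf_area_m2, leaf_area_sd = leaf_area_sd,
    initial_diameter_mm = initial_diameter_mm,
    initial_diameter_sd = initial_diameter_sd,
    sla_m2_g = sla_m2_g, root_shoot_ratio = root_shoot_ratio,
    blank_offset = blank_offset, noise = noise,
    destructive = destructive %||% default_destructive_curves(),
    n_pilot = as.integer(n_pilot),
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  cfg
}

# Treatment-level destructive-sample mean curves: midday water potential
# (MPa), foliar ABA (ng g-1), branch free sugar and starch (% dry weight) at
# the destructive timepoints. Qualitative emulation: severe stress drives psi
# towards -3.8 MPa, doubles ABA mid-drought, doubles free sugar while starch
# is depleted, all relaxing to control levels within days of rewatering.
default_destructive_curves <- function() {
  days <- c(0, 14, 28, 30, 42, 63)
  rbind(
    data.frame(treatment = "control", day = days,
               psi_md_mpa = rep(-1.0, 6), aba_ng_g = rep(100, 6),
               sugar_pct_dw = rep(3.5, 6), starch_pct_dw = rep(3.2, 6)),
    data.frame(treatment = "mild", day = days,
               psi_md_mpa = c(-1.0, -1.1, -1.2, -1.0, -1.0, -1.0),
               aba_ng_g = c(100, 110, 115, 100, 100, 100),
               sugar_pct_dw = c(3.5, 3.7, 3.8, 3.5, 3.5, 3.5),
               starch_pct_dw = c(3.2, 3.0, 2.9, 3.2, 3.2, 3.2)),
    data.frame(treatment = "severe", day = days,
               psi_md_mpa = c(-1.0, -2.5, -3.8, -1.1, -1.0, -1.0),
               aba_ng_g = c(100, 250, 230, 105, 100, 100),
               sugar_pct_dw = c(3.5, 8.0, 5.5, 3.6, 3.5, 3.5),
               starch_pct_dw = c(3.2, 1.0, 0.0, 3.2, 4.1, 3.3))
  )
}

# Half-sine light curve over the photoperiod (zero outside it).
photoperiod_shape <- function(hour, photoperiod) {
  p0 <- photoperiod[1]
  p1 <- photoperiod[2]
  ifelse(hour >= p0 & hour < p1, sin(pi * (hour - p0) / (p1 - p0)), 0)
}

# Drought-effect multiplier at fractional experiment day `day` for one
# treatment: linear ramp 1 -> drought_end over the drought, then linear ramp
# to recovery_end over recovery_ramp_days, constant afterwards.
drought_multiplier <- function(day, treatment, cfg) {
  de <- cfg$drought_end_multiplier[[treatment]]
  re <- cfg$recovery_end_multiplier[[treatment]]
  ifelse(day < cfg$drought_days,
         1 + (de - 1) * day / cfg$drought_days,
         de + (re - de) * pmin(1, (day - cfg$drought_days) / cfg$recovery_ramp_days))
}

# Water-status multiplier controlling reversible stem contraction: follows
# the drought ramp but relaxes back to 1 within ~2 days of rewatering
# (water potential recovers much faster than gas exchange).
water_status_multiplier <- function(day, treatment, cfg) {
  de <- cfg$drought_end_multiplier[[treatment]]
  ifelse(day < cfg$drought_days,
         1 + (de - 1) * day / cfg$drought_days,
         de + (1 - de) * pmin(1, (day - cfg$drought_days) / 2))
}

# True daily basal-area growth rate (mm2 d-1) for integer experiment day.
true_growth_rate <- function(day_int, treatment, cfg) {
  dd <- cfg$drought_days
  delay <- cfg$growth_resume_delay[[treatment]]
  ifelse(day_int < dd,
         cfg$growth_drought[[treatment]],
         ifelse(day_int - dd < delay, 0, cfg$growth_recovery[[treatment]]))
}

make_tree_meta <- function(cfg) {
  rows <- list()
  for (tt in cfg$treatments) {
    for (i in seq_len(cfg$n_trees[[tt]])) {
      id <- sprintf("%s_%02d", tt, i)
      meta <- with_seed(stream_seed(cfg$seed, paste0("meta/", id)), {
        la <- max(0.02, rnorm(1, cfg$leaf_area_m2, cfg$leaf_area_sd))
        d0 <- max(3, rnorm(1, cfg$initial_diameter_mm, cfg$initial_diameter_sd))
        c(la = la, d0 = d0)
      })
      leaf_mass <- meta[["la"]] / cfg$sla_m2_g
      shoot_wood <- 1.5 * leaf_mass
      root_mass <- cfg$root_shoot_ratio[[tt]] * (leaf_mass + shoot_wood)
      rows[[id]] <- data.frame(
        tree_id = id, treatment = tt,
        leaf_area_m2 = meta[["la"]],
        initial_diameter_mm = meta[["d0"]],
        dry_mass_leaf_g = leaf_mass,
        dry_mass_shoot_wood_g = shoot_wood,
        dry_mass_root_g = root_mass,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build the measured sample stream of one chamber by inverting the flux mass
# balance: the dry-basis differential implied by the true flux, plus the
# constant background offset, diluted by the sample-stream water content.
# Inversion of the transpiration formula gives the sample H2O content that
# reproduces the true leaf-area transpiration exactly.
chamber_stream <- function(times, tree_id, compartment, f_true, e_true, la,
                           t_air, par, cfg, noisy = TRUE) {
  n <- length(times)
  c_ref_dry <- cfg$c_ref_ppm / (1 - cfg$w_ref_mmol / 1000)
  dC <- -(f_true / cfg$flow_mol_s) * 1e6 + cfg$blank_offset[["co2_ppm"]]
  r <- cfg$w_ref_mmol / 1000
  K <- (e_true * la / 1000) / cfg$flow_mol_s
  y <- (r + K) / (1 + K)
  dw <- (y * 1000 - cfg$w_ref_mmol) + cfg$blank_offset[["h2o_mmol"]]
  w_nf <- cfg$w_ref_mmol + dw
  c_wet_nf <- (c_ref_dry + dC) * (1 - w_nf / 1000)
  eps <- with_seed(stream_seed(cfg$seed, paste("chamber", tree_id, compartment, sep = "/")), {
    list(c = rnorm(n, 0, cfg$noise[["co2_ppm"]]),
         w = rnorm(n, 0, cfg$noise[["h2o_mmol"]]))
  })
  if (!noisy) eps <- list(c = 0, w = 0)
  data.frame(
    timestamp = times, tree_id = tree_id, compartment = compartment,
    c_ref_ppm = cfg$c_ref_ppm, c_sample_ppm = c_wet_nf + eps$c,
    w_ref_mmol = cfg$w_ref_mmol, w_sample_mmol = w_nf + eps$w,
    flow_mol_s = cfg$flow_mol_s, t_air_c = t_air, p_kpa = cfg$p_kpa,
    par_umol = par, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic drought-recovery chamber dataset
#'
#' Produces chamber gas-exchange records for every tree x compartment x
#' timestamp plus two blank chambers, dendrometer displacement traces, tree
#' metadata, soil water content traces, periodic destructive samples, and the
#' retained ground truth. Sample-stream concentrations are derived by
#' inverting the chamber mass balance from the true fluxes, adding water
#' dilution by the prescribed transpiration, the configured background
#' offsets, and Gaussian measurement noise. Fully reproducible: a fixed
#' config and seed yields bit-identical output, and per-stream child seeds
#' make every tree's streams independent of how many other trees exist.
#'
#' @param config a [scenario_config()] object.
#' @return a list of class `tree_scenario` with elements `chamber`, `dendro`,
#'   `trees`, `soil`, `destructive`, `truth` (list with `flux`,
#'   `daily_growth`, `multipliers`), and `config`.
#' @examples
#' ds <- generate_scenario(scenario_config(
#'   n_trees = c(control = 1L), drought_days = 2L, recovery_days = 2L))
#' head(ds$chamber)
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  total_days <- cfg$drought_days + cfg$recovery_days
  step_s <- cfg$sampling_interval * 60
  n_step <- as.integer(total_days * 86400 / step_s)
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n_step) - 1) * step_s
  h <- hour_of_day(times)
  day_frac <- as.numeric(difftime(times, t0, units = "days"))
  day_int <- floor(day_frac)
  photo <- photoperiod_shape(h, cfg$photoperiod)
  season <- 1 + cfg$seasonal_amplitude * (2 * day_frac / total_days - 1)

  trees <- make_tree_meta(cfg)

  chamber <- list()
  truth_flux <- list()
  dendro <- list()
  soil <- list()

  for (k in seq_len(nrow(trees))) {
    id <- trees$tree_id[k]
    tt <- trees$treatment[k]
    la <- trees$leaf_area_m2[k]
    d0 <- trees$initial_diameter_mm[k]
    m <- drought_multiplier(day_frac, tt, cfg)

    f_shoot <- m * season * la * (cfg$anet_peak * 1e-6 * photo - cfg$shoot_resp)
    f_root <- -m * season * la * cfg$root_resp
    e_shoot <- m * cfg$e_peak * photo + cfg$e_night
    t_shoot <- cfg$t_air_c + 1.5 * photo + 1.0 * (1 - m) * photo

    chamber[[paste0(id, "/shoot")]] <- chamber_stream(
      times, id, "shoot", f_shoot, e_shoot, la, t_shoot,
      cfg$par_peak * photo, cfg)
    chamber[[paste0(id, "/root")]] <- chamber_stream(
      times, id, "root", f_root, 0, la, cfg$t_air_c, 0, cfg)

    truth_flux[[id]] <- data.frame(
      timestamp = rep(times, 2), tree_id = id,
      compartment = rep(c("shoot", "root"), each = n_step),
      f_co2_mol_s = c(f_shoot, f_root),
      e_mmol_m2_s = c(e_shoot, rep(NA_real_, n_step)),
      stringsAsFactors = FALSE
    )

    # --- dendrometer trace ------------------------------------------------
    rate <- true_growth_rate(day_int, tt, cfg)           # mm2 d-1 per step
    f_day <- cfg$daytime_growth_fraction[[tt]]
    w0 <- cfg$growth_window[1]
    w1 <- cfg$growth_window[2]
    wlen <- w1 - w0
    hr_weight <- ifelse(h >= w0 & h < w1, f_day / wlen, (1 - f_day) / (24 - wlen))
    dt_h <- step_s / 3600
    inc <- rate * hr_weight * dt_h                       # growth over (t_i, t_i+1]
    G <- c(0, cumsum(inc[-n_step]))                      # cumulative at each stamp
    shrink <- cfg$diurnal_shrink_um[[tt]] *
      ifelse(h >= 6 & h < 20, sin(pi * (h - 6) / 14), 0)
    twd_um <- cfg$drought_shrink_um[[tt]] *
      (1 - water_status_multiplier(day_frac, tt, cfg))
    ba0 <- pi * d0^2 / 4
    d_growth <- sqrt(4 * (ba0 + G) / pi)
    d_obs <- d_growth - (shrink + twd_um) / 1000
    eps_d <- with_seed(stream_seed(cfg$seed, paste0("dendro/", id)),
                       rnorm(n_step, 0, cfg$noise[["dendro_um"]]))
    dendro[[id]] <- data.frame(
      timestamp = times, tree_id = id,
      displacement_um = (d_obs - d0) * 1000 + eps_d,
      stringsAsFactors = FALSE
    )

    # --- soil water content ----------------------------------------------
    swc <- switch(tt,
      control = rep(22, n_step),
      mild = ifelse(day_frac < cfg$drought_days,
                    pmax(10, 25 - 15 * day_frac / 14),
                    pmin(22, 10 + 6 * (day_frac - cfg$drought_days))),
      severe = ifelse(day_frac < cfg$drought_days,
                      pmax(0, 25 * (1 - day_frac / 26)),
                      pmin(22, 11 * (day_frac - cfg$drought_days))))
    eps_s <- with_seed(stream_seed(cfg$seed, paste0("soil/", id)),
                       rnorm(n_step, 0, cfg$noise[["swc_pct"]]))
    soil[[id]] <- data.frame(timestamp = times, tree_id = id,
                             swc_pct = pmax(0, swc + eps_s),
                             stringsAsFactors = FALSE)
  }

  # Blank chambers: zero true flux, so they record only the background
  # offsets (one blank serves the shoot sections, one the root sections).
  for (sec in c("shoot", "root")) {
    id <- paste0("blank_", sec)
    chamber[[id]] <- chamber_stream(
      times, id, "blank", rep(0, n_step), rep(0, n_step), 1,
      cfg$t_air_c + 1.5 * photo, cfg$par_peak * photo, cfg)
  }

  # Destructive samples: pilot-tree draws around the treatment mean curves.
  destr <- list()
  for (tt in cfg$treatments) {
    curves <- cfg$destructive[cfg$destructive$treatment == tt, , drop = FALSE]
    if (!nrow(curves)) next
    vals <- with_seed(stream_seed(cfg$seed, paste0("destructive/", tt)), {
      do.call(rbind, lapply(seq_len(nrow(curves)), function(j) {
        data.frame(
          treatment = tt, day = curves$day[j],
          tree_id = sprintf("pilot_%s_%02d", tt, seq_len(cfg$n_pilot)),
          psi_md_mpa = rnorm(cfg$n_pilot, curves$psi_md_mpa[j], 0.15),
          aba_ng_g = pmax(0, rnorm(cfg$n_pilot, curves$aba_ng_g[j], 15)),
          sugar_pct_dw = pmax(0, rnorm(cfg$n_pilot, curves$sugar_pct_dw[j], 0.4)),
          starch_pct_dw = pmax(0, rnorm(cfg$n_pilot, curves$starch_pct_dw[j], 0.4)),
          stringsAsFactors = FALSE
        )
      }))
    })
    destr[[tt]] <- vals
  }
  destructive <- if (length(destr)) do.call(rbind, destr) else
    data.frame(treatment = character(), day = numeric(), tree_id = character(),
               psi_md_mpa = numeric(), aba_ng_g = numeric(),
               sugar_pct_dw = numeric(), starch_pct_dw = numeric())
  if (nrow(destructive)) {
    destructive$date <- as.Date(cfg$start_date) + destructive$day
    destructive <- destructive[, c("date", "day", "treatment", "tree_id",
                                   "psi_md_mpa", "aba_ng_g",
                                   "sugar_pct_dw", "starch_pct_dw")]
  }

  daily_truth <- do.call(rbind, lapply(seq_len(nrow(trees)), function(k) {
    d <- 0:(total_days - 1)
    data.frame(tree_id = trees$tree_id[k],
               date = as.Date(cfg$start_date) + d,
               growth_mm2 = true_growth_rate(d, trees$treatment[k], cfg),
               stringsAsFactors = FALSE)
  }))
  mult_truth <- do.call(rbind, lapply(cfg$treatments, function(tt) {
    d <- 0:(total_days - 1)
    data.frame(treatment = tt, day = d,
               multiplier = drought_multiplier(d, tt, cfg),
               stringsAsFactors = FALSE)
  }))

  chamber <- do.call(rbind, chamber)
  rownames(chamber) <- NULL
  dendro <- do.call(rbind, dendro)
  rownames(dendro) <- NULL
  soil <- do.call(rbind, soil)
  rownames(soil) <- NULL
  truth_flux <- do.call(rbind, truth_flux)
  rownames(truth_flux) <- NULL
  rownames(destructive) <- NULL

  structure(list(
    chamber = chamber, dendro = dendro, trees = trees, soil = soil,
    destructive = destructive,
    truth = list(flux = truth_flux, daily_growth = daily_truth,
                 multipliers = mult_truth),
    config = cfg
  ), class = "tree_scenario")
}

#' @export
print.tree_scenario <- function(x, ...) {
  cat("tree_scenario:",
      nrow(x$trees), "trees,",
      nrow(x$chamber), "chamber records,",
      nrow(x$dendro), "dendrometer records\n")
  cat("treatments:", paste(sprintf("%s (n=%d)", names(x$config$n_trees),
                                   x$config$n_trees), collapse = ", "), "\n")
  invisible(x)
}

#' Write a scenario dataset to a directory of CSV files
#'
#' Writes `chamber.csv`, `dendro.csv`, `trees.csv`, `soil.csv`,
#' `destructive.csv` (UTF-8, ISO-8601 timestamps, one header row) and
#' `truth.json` (ground truth plus the key configuration fields). The files
#' round-trip losslessly through [read_scenario()] to within CSV numeric
#' precision (15 significant digits).
#'
#' @param dataset a `tree_scenario` from [generate_scenario()].
#' @param directory output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(dataset, directory) {
  stopifnot(inherits(dataset, "tree_scenario"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create directory: ", directory, call. = FALSE)
  }
  wr <- function(df, name) {
    if ("timestamp" %in% names(df)) df$timestamp <- format_time(df$timestamp)
    if ("date" %in% names(df)) df$date <- as.character(df$date)
    write.csv(df, file.path(directory, name), row.names = FALSE, quote = FALSE)
  }
  wr(dataset$chamber, "chamber.csv")
  wr(dataset$dendro, "dendro.csv")
  wr(dataset$trees, "trees.csv")
  wr(dataset$soil, "soil.csv")
  wr(dataset$destructive, "destructive.csv")

  truth <- dataset$truth
  truth$flux$timestamp <- format_time(truth$flux$timestamp)
  truth$daily_growth$date <- as.character(truth$daily_growth$date)
  cfg <- dataset$config
  truth$config <- list(
    start_date = cfg$start_date, drought_days = cfg$drought_days,
    recovery_days = cfg$recovery_days, sampling_interval = cfg$sampling_interval,
    seed = cfg$seed, n_trees = as.list(cfg$n_trees),
    recovery_end_multiplier = as.list(cfg$recovery_end_multiplier)
  )
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(directory)
}

#' Read a scenario dataset back from a directory
#'
#' Inverse of [write_scenario()]. `truth.json` is optional (a real-data
#' directory has no ground truth); when absent, `truth` is `NULL` and period
#' dates must be supplied to [run_pipeline()] explicitly.
#'
#' @param directory directory containing the scenario CSV files.
#' @return a list of class `tree_scenario`.
#' @export
read_scenario <- function(directory) {
  need <- c("chamber.csv", "dendro.csv", "trees.csv", "soil.csv")
  miss <- need[!file.exists(file.path(directory, need))]
  if (length(miss)) {
    stop("scenario directory is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rd <- function(name) {
    df <- read.csv(file.path(directory, name), stringsAsFactors = FALSE)
    if ("timestamp" %in% names(df)) df$timestamp <- parse_time(df$timestamp)
    if ("date" %in% names(df)) df$date <- as.Date(df$date)
    df
  }
  out <- list(
    chamber = rd("chamber.csv"), dendro = rd("dendro.csv"),
    trees = rd("trees.csv"), soil = rd("soil.csv"),
    destructive = if (file.exists(file.path(directory, "destructive.csv")))
      rd("destructive.csv") else NULL,
    truth = NULL, config = NULL
  )
  tpath <- file.path(directory, "truth.json")
  if (file.exists(tpath)) {
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth$flux <- as.data.frame(truth$flux, stringsAsFactors = FALSE)
    truth$flux$timestamp <- parse_time(truth$flux$timestamp)
    truth$daily_growth <- as.data.frame(truth$daily_growth, stringsAsFactors = FALSE)
    truth$daily_growth$date <- as.Date(truth$daily_growth$date)
    out$config <- truth$config
    truth$config <- NULL
    out$truth <- truth
  }
  class(out) <- "tree_scenario"
  out
}
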