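# Chamber gas-exchange computation: from raw paired reference/sample
# airstream records to compartment CO2/H2O fluxes and leaf-area normalized
# gas exchange. All internal computation uses dry-basis mole fractions and
# SI molar flow (mol s-1); ppm <-> mol-fraction conversion happens in one
# place. Sign convention: positive CO2 flux = carbon gain by the plant, so
# root (respiring) compartments carry negative fluxes.

#' Convert a moist-air mole fraction to a dry-air basis
#'
#' Water-dilution correction: a gas mole fraction measured in moist air is
#' inflated to its dry-air equivalent, `C_wet / (1 - w/1000)`.
#'
#' @param c_wet mole fraction in moist air (µmol mol-1 moist air).
#' @param w_mmol water vapor content of the same stream (mmol mol-1 moist
#'   air); must satisfy `0 <= w < 1000`.
#' @return dry-basis mole fraction (µmol mol-1 dry air), always `>= c_wet`.
#' @examples
#' dry_mole_fraction(440, 20) # 440 / 0.98
#' @export
dry_mole_fraction <- function(c_wet, w_mmol) {
  if (any(w_mmol >= 1000 | w_mmol < 0, na.rm = TRUE)) {
    stop("invalid humidity: w must lie in [0, 1000) mmol mol-1", call. = FALSE)
  }
  c_wet / (1 - w_mmol / 1000)
}

#' Saturation vapor pressure (Tetens form)
#'
#' `e_sat(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa; conventional and
#' accurate between 0 and 40 deg C.
#'
#' @param t_c air temperature (deg C).
#' @return saturation vapor pressure (kPa).
#' @export
esat_tetens <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

#' Subtract the blank-chamber background from a sample differential
#'
#' Plant-free blank chambers measure the background gas exchange of the
#' chamber system itself; their sample-minus-reference differential is
#' subtracted from the corresponding plant-chamber differential (CO2 and H2O
#' alike). The reference stream is untouched.
#'
#' @param differential sample-minus-reference differential of a plant
#'   chamber (µmol mol-1 for CO2, mmol mol-1 for H2O).
#' @param blank_differential time-matched differential of the blank chamber,
#'   same units.
#' @return corrected differential.
#' @examples
#' background_correct(-10.15, 0.15) # -10.30
#' @export
background_correct <- function(differential, blank_differential) {
  differential - blank_differential
}

#' Compartment molar CO2 flux from the chamber mass balance
#'
#' `F = -flow * (C_sample - C_ref) * 1e-6`, with mole fractions on a dry
#' basis in µmol mol-1 and flow in mol s-1. Positive F means the compartment
#' removes CO2 from the airstream (net uptake); a respiring compartment
#' enriches the sample stream and yields a negative flux.
#'
#' @param flow_mol_s molar air flow through the chamber (mol s-1), `> 0`.
#' @param c_sample_dry,c_ref_dry dry-basis CO2 mole fractions of sample and
#'   reference streams (µmol mol-1 dry air); the sample value should already
#'   be background-corrected.
#' @return molar CO2 flux (mol CO2 s-1).
#' @examples
#' compartment_co2_flux(0.01, 440, 450) # +1e-7 (net uptake)
#' @export
compartment_co2_flux <- function(flow_mol_s, c_sample_dry, c_ref_dry) {
  if (any(flow_mol_s <= 0, na.rm = TRUE)) {
    stop("flow must be > 0 mol s-1", call. = FALSE)
  }
  -flow_mol_s * (c_sample_dry - c_ref_dry) * 1e-6
}

#' Transpiration per unit leaf area
#'
#' Well-stirred chamber water mass balance:
#' `E = flow * ((w_sample - w_ref)/1000) / (1 - w_sample/1000) / leaf_area`,
#' reported in mmol H2O m-2 leaf s-1. Positive when the plant adds water
#' vapor to the airstream.
#'
#' @param flow_mol_s molar air flow (mol s-1).
#' @param w_sample_mmol,w_ref_mmol sample and reference stream water content
#'   (mmol mol-1 moist air); the sample value should be background-corrected.
#' @param leaf_area_m2 leaf area of the tree (m2), `> 0`.
#' @return transpiration (mmol H2O m-2 s-1).
#' @export
transpiration <- function(flow_mol_s, w_sample_mmol, w_ref_mmol, leaf_area_m2) {
  if (any(leaf_area_m2 <= 0, na.rm = TRUE)) {
    stop("leaf_area_m2 must be > 0", call. = FALSE)
  }
  dw <- (w_sample_mmol - w_ref_mmol) / 1000
  flow_mol_s * dw / (1 - w_sample_mmol / 1000) / leaf_area_m2 * 1000
}

#' Stomatal conductance to water vapor
#'
#' `g_sw = E / dw`, where `dw = (e_sat(T_air) - e_air) / P` is the
#' leaf-to-air water mole-fraction gradient, `e_air = w_sample * P / 1000`,
#' and saturation follows [esat_tetens()]. Leaf temperature is assumed equal
#' to air temperature (ventilated chambers, no boundary-layer term). Points
#' with a non-positive gradient (saturated chamber air) are undefined and
#' returned as `NA`.
#'
#' @param e_mmol transpiration (mmol m-2 s-1).
#' @param t_air_c chamber air temperature (deg C).
#' @param w_sample_mmol sample-stream water content (mmol mol-1 moist air).
#' @param p_kpa ambient pressure (kPa).
#' @return stomatal conductance (mmol m-2 s-1), `NA` where undefined.
#' @export
stomatal_conductance <- function(e_mmol, t_air_c, w_sample_mmol, p_kpa) {
  e_air <- w_sample_mmol / 1000 * p_kpa
  vpd <- esat_tetens(t_air_c) - e_air
  dw <- vpd / p_kpa
  out <- e_mmol / dw
  out[!is.na(dw) & dw <= 0] <- NA_real_
  out
}

#' Net assimilation per unit leaf area and intrinsic water-use efficiency
#'
#' `A_net = F * 1e6 / leaf_area` (µmol CO2 m-2 leaf s-1); defined for shoot
#' compartments. `WUE_i = A_net / (g_sw / 1000)` (µmol CO2 mol-1 H2O) and may
#' be negative under net daytime respiration; it is undefined (`NA`) where
#' `g_sw` is zero or missing.
#'
#' @param f_co2_mol_s shoot compartment CO2 flux (mol s-1).
#' @param leaf_area_m2 leaf area (m2), `> 0`.
#' @return `net_assimilation()`: A_net in µmol m-2 s-1.
#' @export
net_assimilation <- function(f_co2_mol_s, leaf_area_m2) {
  if (any(leaf_area_m2 <= 0, na.rm = TRUE)) {
    stop("leaf_area_m2 must be > 0", call. = FALSE)
  }
  f_co2_mol_s * 1e6 / leaf_area_m2
}

#' @rdname net_assimilation
#' @param anet_umol net assimilation (µmol m-2 s-1).
#' @param gsw_mmol stomatal conductance (mmol m-2 s-1).
#' @return `wue_i()`: intrinsic water-use efficiency in µmol CO2 mol-1 H2O.
#' @export
wue_i <- function(anet_umol, gsw_mmol) {
  out <- anet_umol / (gsw_mmol / 1000)
  out[!is.na(gsw_mmol) & gsw_mmol <= 0] <- NA_real_
  out
}

#' Compute the full flux table from raw chamber records
#'
#' Applies, in order: water-dilution correction of both streams, time-matched
#' blank-chamber background subtraction of the sample-minus-reference
#' differentials (nearest blank within `blank_tolerance_min`), the chamber
#' CO2 mass balance, and the leaf-area normalized derivations (E, g_sw,
#' A_net, WUE_i, chamber VPD) for shoot compartments. Root rows carry the
#' compartment flux only. Undefined points are `NA`, never zero.
#'
#' Blank chambers are identified by `compartment == "blank"`; a blank whose
#' `tree_id` ends in `_shoot` or `_root` serves that chamber section, any
#' other blank serves all sections.
#'
#' @param chamber chamber record table (columns `timestamp`, `tree_id`,
#'   `compartment`, `c_ref_ppm`, `c_sample_ppm`, `w_ref_mmol`,
#'   `w_sample_mmol`, `flow_mol_s`, `t_air_c`, `p_kpa`, `par_umol`).
#' @param trees tree metadata with `tree_id` and `leaf_area_m2`.
#' @param blank_tolerance_min maximum time offset (minutes) between a record
#'   and its matched blank measurement; records without a blank inside the
#'   window are masked.
#' @return data.frame with columns `timestamp`, `tree_id`, `compartment`,
#'   `f_co2_mol_s`, `e_mmol_m2_s`, `gsw_mmol_m2_s`, `anet_umol_m2_s`,
#'   `wuei_umol_mol`, `vpd_kpa`.
#' @export
compute_fluxes <- function(chamber, trees, blank_tolerance_min = 90) {
  assert_columns(chamber, c("timestamp", "tree_id", "compartment",
                            "c_ref_ppm", "c_sample_ppm", "w_ref_mmol",
                            "w_sample_mmol", "flow_mol_s", "t_air_c",
                            "p_kpa"), "chamber table")
  assert_columns(trees, c("tree_id", "leaf_area_m2"), "trees table")
  ch <- chamber
  ch$timestamp <- parse_time(ch$timestamp)

  dry_s <- dry_mole_fraction(ch$c_sample_ppm, ch$w_sample_mmol)
  dry_r <- dry_mole_fraction(ch$c_ref_ppm, ch$w_ref_mmol)
  dC_raw <- dry_s - dry_r
  dw_raw <- ch$w_sample_mmol - ch$w_ref_mmol

  is_blank <- ch$compartment == "blank"
  if (!any(is_blank)) {
    stop("no blank-chamber records found; background correction impossible",
         call. = FALSE)
  }
  bsec <- sub("^blank_", "", ch$tree_id[is_blank])
  bsec[!bsec %in% c("shoot", "root")] <- "any"
  tol_s <- blank_tolerance_min * 60

  blank_for <- function(section, query_times) {
    pick <- bsec == section
    if (!any(pick)) pick <- bsec == "any"
    if (!any(pick)) pick <- rep(TRUE, sum(is_blank))
    bt <- ch$timestamp[is_blank][pick]
    o <- order(bt)
    idx <- nearest_index(query_times, bt[o], tol_s)
    list(dC = dC_raw[is_blank][pick][o][idx],
         dw = dw_raw[is_blank][pick][o][idx])
  }

  dC <- rep(NA_real_, nrow(ch))
  dw <- rep(NA_real_, nrow(ch))
  for (sec in c("shoot", "root")) {
    rows <- which(ch$compartment == sec)
    if (!length(rows)) next
    bl <- blank_for(sec, ch$timestamp[rows])
    dC[rows] <- background_correct(dC_raw[rows], bl$dC)
    dw[rows] <- background_correct(dw_raw[rows], bl$dw)
  }

  plant <- ch$compartment %in% c("shoot", "root")
  out <- ch[plant, c("timestamp", "tree_id", "compartment")]
  f <- -ch$flow_mol_s[plant] * dC[plant] * 1e-6
  out$f_co2_mol_s <- f

  la <- trees$leaf_area_m2[match(out$tree_id, trees$tree_id)]
  shoot <- out$compartment == "shoot"
  e <- gsw <- anet <- wuei <- vpd <- rep(NA_real_, nrow(out))
  if (any(shoot)) {
    if (anyNA(la[shoot])) {
      stop("shoot records reference trees with no leaf area metadata",
           call. = FALSE)
    }
    w_corr <- ch$w_ref_mmol[plant][shoot] + dw[plant][shoot]
    flow <- ch$flow_mol_s[plant][shoot]
    e[shoot] <- transpiration(flow, w_corr, ch$w_ref_mmol[plant][shoot], la[shoot])
    tair <- ch$t_air_c[plant][shoot]
    p <- ch$p_kpa[plant][shoot]
    vpd[shoot] <- esat_tetens(tair) - w_corr / 1000 * p
    gsw[shoot] <- stomatal_conductance(e[shoot], tair, w_corr, p)
    anet[shoot] <- net_assimilation(f[shoot], la[shoot])
    wuei[shoot] <- wue_i(anet[shoot], gsw[shoot])
  }
  out$e_mmol_m2_s <- e
  out$gsw_mmol_m2_s <- gsw
  out$anet_umol_m2_s <- anet
  out$wuei_umol_mol <- wuei
  out$vpd_kpa <- vpd
  rownames(out) <- NULL
  out
}

#' Resample per-chamber series onto a common clock
#'
#' The chamber multiplexer visits chambers sequentially, so raw per-chamber
#' timestamps are irregular. Each series (one `tree_id` x `compartment`
#' combination, every numeric column) is linearly interpolated onto a common
#' clock at `interval_min` spacing. Output points bracketed by an input gap
#' longer than `gap_max_min` are left missing rather than interpolated, as
#' are points outside the observed range. Already-gridded input passes
#' through unchanged.
#'
#' @param x long table with a `timestamp` column, id columns, and numeric
#'   value columns.
#' @param interval_min target clock spacing (minutes).
#' @param gap_max_min longest input gap (minutes) across which interpolation
#'   is allowed.
#' @param id_cols columns identifying a series.
#' @return table with the same columns on the common clock.
#' @export
resample_cycle <- function(x, interval_min = 60, gap_max_min = 180,
                           id_cols = c("tree_id", "compartment")) {
  assert_columns(x, c("timestamp", id_cols), "series table")
  x$timestamp <- parse_time(x$timestamp)
  if (nrow(x) < 2) stop("need at least 2 points to resample", call. = FALSE)
  step <- interval_min * 60
  gap_s <- gap_max_min * 60
  t_min <- floor(as.numeric(min(x$timestamp)) / step) * step
  t_max <- ceiling(as.numeric(max(x$timestamp)) / step) * step
  grid <- seq(t_min, t_max, by = step)
  val_cols <- setdiff(names(x), c("timestamp", id_cols))
  val_cols <- val_cols[vapply(x[val_cols], is.numeric, logical(1))]

  key <- do.call(paste, c(x[id_cols], sep = "\r"))
  pieces <- lapply(split(seq_len(nrow(x)), key), function(rows) {
    xi <- x[rows, , drop = FALSE]
    xi <- xi[order(xi$timestamp), , drop = FALSE]
    tn <- as.numeric(xi$timestamp)
    out <- xi[rep(1L, length(grid)), c(id_cols), drop = FALSE]
    out$timestamp <- as.POSIXct(grid, origin = "1970-01-01", tz = "UTC")
    for (v in val_cols) {
      out[[v]] <- resample_column(tn, xi[[v]], grid, gap_s)
    }
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[, c("timestamp", id_cols, val_cols)]
  rownames(out) <- NULL
  out
}

# Interpolate one column onto the grid, masking long gaps and extrapolation.
resample_column <- function(tn, v, grid, gap_s) {
  ok <- !is.na(v)
  if (sum(ok) < 2) return(rep(NA_real_, length(grid)))
  tv <- tn[ok]
  vv <- v[ok]
  out <- approx(tv, vv, xout = grid, ties = "ordered")$y
  i <- findInterval(grid, tv)
  inside <- i >= 1 & i < length(tv)
  gap <- rep(FALSE, length(grid))
  gap[inside] <- (tv[i[inside] + 1] - tv[i[inside]]) > gap_s &
    grid[inside] != tv[i[inside]]
  out[gap] <- NA_real_
  out
}
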