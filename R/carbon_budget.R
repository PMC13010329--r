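# Daily and cumulative whole-plant carbon budgeting. Daily integration is
# mean-of-valid-samples x 86400 s (the daily-average molar flux times the
# molar mass of carbon), not trapezoidal; missing samples are excluded from
# the mean and never enter as zeros.

#' Daily per-tree carbon rates from a flux series
#'
#' For every tree and UTC day, the daily compartment carbon rate is the mean
#' valid compartment flux (mol CO2 s-1) times `12.01 g mol-1` times
#' `86400 s d-1`, in g C d-1. The whole-plant rate is the sum of shoot and
#' root rates. Days whose joint shoot/root coverage falls below
#' `min_valid_hours` are flagged; days with no valid samples in a
#' compartment get `NA` rates and are flagged.
#'
#' @param flux flux table from [compute_fluxes()] (ideally after
#'   [resample_cycle()]), with `timestamp`, `tree_id`, `compartment`,
#'   `f_co2_mol_s`.
#' @param min_valid_hours minimum joint valid hours for an unflagged day.
#' @param interval_min sample spacing of the input (minutes), used to turn
#'   sample counts into hours.
#' @return data.frame with `date`, `tree_id`, `c_shoot`, `c_root`, `c_plant`
#'   (g C d-1), `n_valid_hours`, `flagged`.
#' @export
daily_carbon <- function(flux, min_valid_hours = 12, interval_min = 60) {
  assert_columns(flux, c("timestamp", "tree_id", "compartment", "f_co2_mol_s"),
                 "flux table")
  d <- flux[flux$compartment %in% c("shoot", "root"), ]
  d$date <- date_utc(parse_time(d$timestamp))
  key <- paste(d$tree_id, d$date, sep = "\r")
  rows <- split(seq_len(nrow(d)), key)
  out <- do.call(rbind, lapply(rows, function(idx) {
    di <- d[idx, ]
    fs <- di$f_co2_mol_s[di$compartment == "shoot"]
    fr <- di$f_co2_mol_s[di$compartment == "root"]
    ns <- sum(!is.na(fs))
    nr <- sum(!is.na(fr))
    cs <- if (ns > 0) mean(fs, na.rm = TRUE) * M_CARBON * S_DAY else NA_real_
    cr <- if (nr > 0) mean(fr, na.rm = TRUE) * M_CARBON * S_DAY else NA_real_
    data.frame(date = di$date[1], tree_id = di$tree_id[1],
               c_shoot = cs, c_root = cr, c_plant = cs + cr,
               n_valid_hours = min(ns, nr) * interval_min / 60,
               stringsAsFactors = FALSE)
  }))
  out$flagged <- is.na(out$c_plant) | out$n_valid_hours < min_valid_hours
  out <- out[order(out$tree_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Running cumulative carbon per tree
#'
#' Fills `c_cum`, the running sum of daily whole-plant carbon rates per tree
#' in date order. Missing (`NA`) days contribute zero to the sum but remain
#' flagged.
#'
#' @param daily output of [daily_carbon()].
#' @return the input with a `c_cum` column (g C).
#' @export
cumulative_carbon <- function(daily) {
  assert_columns(daily, c("date", "tree_id", "c_plant"), "daily carbon table")
  daily <- daily[order(daily$tree_id, daily$date), ]
  pieces <- lapply(split(daily, daily$tree_id), function(di) {
    if (anyDuplicated(di$date)) {
      stop("duplicate dates for tree ", di$tree_id[1], call. = FALSE)
    }
    contrib <- ifelse(is.na(di$c_plant), 0, di$c_plant)
    di$c_cum <- cumsum(contrib)
    di
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Treatment-level period summary of daily carbon rates
#'
#' Per-individual-first averaging: for each tree, the mean daily rate of each
#' compartment within the period window; then the treatment mean and standard
#' error (sd/sqrt(n)) across trees. The SE of a single-tree group is
#' reported missing. Flagged days are excluded.
#'
#' @param daily output of [daily_carbon()] (optionally with `c_cum`).
#' @param periods named list of `c(start_date, end_date)` (inclusive), e.g.
#'   `list(drought = ..., recovery = ..., experimental = ...)`.
#' @param trees tree metadata with `tree_id` and `treatment`.
#' @return data.frame with `treatment`, `compartment` (`shoot`, `root`,
#'   `plant`), `period`, `mean_rate`, `se_rate` (g C d-1), `n_trees`.
#' @export
period_summary <- function(daily, periods, trees) {
  assert_columns(daily, c("date", "tree_id", "c_shoot", "c_root", "c_plant"),
                 "daily carbon table")
  assert_columns(trees, c("tree_id", "treatment"), "trees table")
  use <- if ("flagged" %in% names(daily)) daily[!daily$flagged, ] else daily
  out <- list()
  for (pn in names(periods)) {
    win <- as.Date(periods[[pn]])
    dp <- use[use$date >= win[1] & use$date <= win[2], ]
    for (comp in c("shoot", "root", "plant")) {
      col <- paste0("c_", comp)
      per_tree <- tapply(dp[[col]], dp$tree_id, mean, na.rm = TRUE)
      pt <- data.frame(tree_id = names(per_tree), value = as.numeric(per_tree),
                       stringsAsFactors = FALSE)
      pt$treatment <- trees$treatment[match(pt$tree_id, trees$tree_id)]
      for (tt in unique(trees$treatment)) {
        v <- pt$value[pt$treatment %in% tt & !is.na(pt$value)]
        if (!length(v)) {
          stop("empty treatment group '", tt, "' in period '", pn, "'",
               call. = FALSE)
        }
        out[[length(out) + 1L]] <- data.frame(
          treatment = tt, compartment = comp, period = pn,
          mean_rate = mean(v), se_rate = se_of_mean(v),
          n_trees = length(v), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Carbon accumulation rate over the final days of a series
#'
#' Ordinary least-squares slope of cumulative carbon versus day over the
#' final `window_days` of each tree's series — the standard way to express
#' the end-of-recovery daily accumulation rate.
#'
#' @param daily output of [cumulative_carbon()].
#' @param window_days length of the terminal fitting window (days); at least
#'   3 days must fall in it.
#' @return data.frame with `tree_id`, `slope` (g C d-1), `se`.
#' @export
tail_accumulation_rate <- function(daily, window_days = 10) {
  assert_columns(daily, c("date", "tree_id", "c_cum"), "cumulative table")
  pieces <- lapply(split(daily, daily$tree_id), function(di) {
    di <- di[order(di$date), ]
    if (window_days > nrow(di)) {
      stop("window exceeds series length for tree ", di$tree_id[1],
           call. = FALSE)
    }
    di <- di[seq(nrow(di) - window_days + 1, nrow(di)), ]
    if (nrow(di) < 3) stop("need >= 3 days in the tail window", call. = FALSE)
    fit <- ols_slope(as.numeric(di$date), di$c_cum)
    data.frame(tree_id = di$tree_id[1], slope = fit[["slope"]],
               se = fit[["se"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
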