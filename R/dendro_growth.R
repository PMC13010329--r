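# Dendrometer processing: displacement -> absolute diameter -> basal area,
# zero-growth decomposition into irreversible growth and tree water deficit,
# diurnal growth partitioning, and Huber-value tracking.
#
# The zero-growth concept assumes no growth while the stem is dehydrated,
# i.e. while its size sits below the previously recorded maximum: cumulative
# growth is the running maximum of basal area relative to the series start,
# and tree water deficit (TWD) is the running maximum minus the current
# basal area. Growth increments attach to the interval since the previous
# sample and are attributed to the interval's start time for daily and
# hourly aggregation.

#' Convert dendrometer displacement to diameter and basal area
#'
#' Absolute diameter is the initial caliper diameter plus displacement
#' (`diameter = initial + displacement/1000` mm); basal area assumes a
#' circular cross-section (`pi * diameter^2 / 4`, mm2).
#'
#' @param dendro displacement table with `timestamp`, `tree_id`,
#'   `displacement_um`.
#' @param trees tree metadata with `tree_id` and `initial_diameter_mm`.
#' @return the input with `diameter_mm` and `basal_area_mm2` columns.
#' @examples
#' d <- data.frame(timestamp = Sys.time(), tree_id = "t1", displacement_um = 0)
#' m <- data.frame(tree_id = "t1", initial_diameter_mm = 10)
#' to_basal_area(d, m)$basal_area_mm2 # pi * 100 / 4
#' @export
to_basal_area <- function(dendro, trees) {
  assert_columns(dendro, c("timestamp", "tree_id", "displacement_um"),
                 "dendro table")
  assert_columns(trees, c("tree_id", "initial_diameter_mm"), "trees table")
  d0 <- trees$initial_diameter_mm[match(dendro$tree_id, trees$tree_id)]
  if (anyNA(d0)) {
    stop("dendro records reference trees without initial diameter", call. = FALSE)
  }
  if (any(d0 <= 0)) stop("initial diameter must be > 0", call. = FALSE)
  out <- dendro
  out$timestamp <- parse_time(out$timestamp)
  out$diameter_mm <- d0 + out$displacement_um / 1000
  if (any(out$diameter_mm <= 0, na.rm = TRUE)) {
    stop("non-positive diameter after applying displacement", call. = FALSE)
  }
  out$basal_area_mm2 <- pi * out$diameter_mm^2 / 4
  out
}

#' Zero-growth decomposition of a basal-area series
#'
#' Splits each tree's basal-area trace into irreversible growth and
#' reversible dehydration: `growth_cum(t) = runmax(basal_area)(t) -
#' basal_area(t0)` and `twd(t) = runmax(t) - basal_area(t)`. Growth is
#' non-decreasing by construction and accrues only when the stem exceeds its
#' previous maximum; the running maximum is never reset, so post-drought
#' rehydration back to the old maximum registers no growth.
#'
#' @param ba output of [to_basal_area()]; timestamps must be strictly
#'   increasing within each tree.
#' @return data.frame with `timestamp`, `tree_id`, `basal_area_mm2`,
#'   `growth_cum_mm2`, `growth_increment_mm2` (growth since the previous
#'   sample), `twd_mm2`.
#' @export
zero_growth <- function(ba) {
  assert_columns(ba, c("timestamp", "tree_id", "basal_area_mm2"), "basal-area table")
  pieces <- lapply(split(ba, ba$tree_id), function(bi) {
    if (is.unsorted(bi$timestamp, strictly = TRUE)) {
      stop("timestamps not strictly increasing for tree ", bi$tree_id[1],
           call. = FALSE)
    }
    rm_ <- cummax(bi$basal_area_mm2)
    data.frame(
      timestamp = bi$timestamp, tree_id = bi$tree_id,
      basal_area_mm2 = bi$basal_area_mm2,
      growth_cum_mm2 = rm_ - bi$basal_area_mm2[1],
      growth_increment_mm2 = c(NA_real_, diff(rm_)),
      twd_mm2 = rm_ - bi$basal_area_mm2,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Daily growth from a zero-growth series
#'
#' Sums growth increments per tree and UTC day, attributing each increment
#' to the day in which its interval starts.
#'
#' @param growth output of [zero_growth()].
#' @return data.frame with `tree_id`, `date`, `growth_mm2` (mm2 d-1).
#' @export
daily_growth <- function(growth) {
  assert_columns(growth, c("timestamp", "tree_id", "growth_increment_mm2"),
                 "growth table")
  pieces <- lapply(split(growth, growth$tree_id), function(gi) {
    gi <- gi[order(gi$timestamp), ]
    if (nrow(gi) < 2) return(NULL)
    inc <- gi$growth_increment_mm2[-1]
    day <- date_utc(gi$timestamp[-nrow(gi)])   # interval start
    s <- tapply(inc, day, sum, na.rm = TRUE)
    data.frame(tree_id = gi$tree_id[1], date = as.Date(names(s)),
               growth_mm2 = as.numeric(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Mask the first day of recovery in a daily-growth table
#'
#' Rewatered stems rehydrate to (and can briefly overshoot) their previous
#' maximum within the first day of recovery; that apparent expansion is
#' water, not growth. Reported growth therefore starts on the second day of
#' recovery: the first recovery day is masked (`growth_mm2` set `NA`,
#' `masked = TRUE`).
#'
#' @param dg output of [daily_growth()].
#' @param recovery_start `Date` of the first recovery day.
#' @return the input with a `masked` column and the masked day's growth `NA`.
#' @export
recovery_mask <- function(dg, recovery_start) {
  assert_columns(dg, c("tree_id", "date", "growth_mm2"), "daily growth table")
  out <- dg
  out$masked <- out$date == as.Date(recovery_start)
  out$growth_mm2[out$masked] <- NA_real_
  out
}

#' Diurnal partitioning of growth into day and night windows
#'
#' Builds the mean diurnal growth composite across all trees and days in the
#' input: for each hour of day, the mean growth increment attributed to that
#' hour. The daytime rate is the OLS slope of the cumulative composite
#' versus hour inside `window` (mm2 h-1); the nighttime rate is the slope
#' over the complementary (wrapped) hours; `daytime_fraction` is daytime
#' growth over total daily growth, reported only when total growth is
#' positive.
#'
#' @param growth output of [zero_growth()] (one or several trees; composite
#'   pools everything, so pass one treatment's trees for a treatment-level
#'   partition).
#' @param window daytime window `c(start_hour, end_hour)`, half-open.
#' @return list with `daytime_rate`, `nighttime_rate` (mm2 h-1),
#'   `daytime_fraction`, and the hourly `composite` data.frame.
#' @export
diurnal_partition <- function(growth, window = c(5, 17)) {
  assert_columns(growth, c("timestamp", "tree_id", "growth_increment_mm2"),
                 "growth table")
  if (window[1] >= window[2]) stop("empty daytime window", call. = FALSE)
  pieces <- lapply(split(growth, growth$tree_id), function(gi) {
    gi <- gi[order(gi$timestamp), ]
    if (nrow(gi) < 2) return(NULL)
    data.frame(hour = floor(hour_of_day(gi$timestamp[-nrow(gi)])),
               inc = gi$growth_increment_mm2[-1])
  })
  d <- do.call(rbind, pieces)
  comp <- tapply(d$inc, d$hour, mean, na.rm = TRUE)
  composite <- data.frame(hour = as.numeric(names(comp)),
                          mean_increment_mm2 = as.numeric(comp))
  is_day <- composite$hour >= window[1] & composite$hour < window[2]
  day_growth <- sum(composite$mean_increment_mm2[is_day])
  total <- sum(composite$mean_increment_mm2)
  frac <- if (total > 0) day_growth / total else NA_real_

  slope_of <- function(hours_ordered) {
    rows <- match(hours_ordered, composite$hour)
    rows <- rows[!is.na(rows)]
    if (length(rows) < 3) return(NA_real_)
    y <- cumsum(composite$mean_increment_mm2[rows])
    ols_slope(seq_along(rows), y)[["slope"]]
  }
  day_hours <- window[1]:(window[2] - 1)
  night_hours <- setdiff(0:23, day_hours)
  # order night hours continuously across midnight, starting at window end
  night_hours <- c(night_hours[night_hours >= window[2]],
                   night_hours[night_hours < window[1]])
  list(daytime_rate = slope_of(day_hours),
       nighttime_rate = slope_of(night_hours),
       daytime_fraction = frac,
       composite = composite)
}

#' Huber-value series from basal area and leaf area
#'
#' The Huber value is the ratio of sapwood cross-sectional area to leaf
#' area, a proxy for hydraulic supply relative to transpirational demand.
#' Whole basal area (over bark) stands in for sapwood; by default the
#' running maximum of basal area (the zero-growth stem size, insensitive to
#' reversible shrinkage), configurable to the instantaneous basal area.
#' Units: mm2 sapwood per cm2 leaf area, which puts juvenile conifers near
#' an operating point of ~0.08.
#'
#' @param ba output of [to_basal_area()].
#' @param trees tree metadata with `tree_id`, `leaf_area_m2` (assumed
#'   constant over the experiment).
#' @param sapwood_rule `"running_max"` (default) or `"instantaneous"`.
#' @return data.frame with `timestamp`, `tree_id`, `sapwood_area_mm2`,
#'   `hv_mm2_cm2`.
#' @export
huber_series <- function(ba, trees, sapwood_rule = c("running_max", "instantaneous")) {
  sapwood_rule <- match.arg(sapwood_rule)
  assert_columns(ba, c("timestamp", "tree_id", "basal_area_mm2"), "basal-area table")
  assert_columns(trees, c("tree_id", "leaf_area_m2"), "trees table")
  la <- trees$leaf_area_m2[match(ba$tree_id, trees$tree_id)]
  if (anyNA(la) || any(la <= 0)) {
    stop("every tree needs a positive leaf area", call. = FALSE)
  }
  pieces <- lapply(split(seq_len(nrow(ba)), ba$tree_id), function(rows) {
    bi <- ba[rows, ]
    o <- order(bi$timestamp)
    sw <- bi$basal_area_mm2[o]
    if (sapwood_rule == "running_max") sw <- cummax(sw)
    data.frame(timestamp = bi$timestamp[o], tree_id = bi$tree_id[o],
               sapwood_area_mm2 = sw,
               hv_mm2_cm2 = sw / (la[rows][o] * 1e4),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Start-of-day Huber value
#'
#' Samples the Huber-value series at a fixed early-morning hour per tree and
#' day (daytime growth capacity relates to hydraulic supply at the start of
#' the day). Uses the nearest sample within `tol_min` of the target hour,
#' missing otherwise.
#'
#' @param hv output of [huber_series()].
#' @param hour target hour of day.
#' @param tol_min matching tolerance (minutes).
#' @return data.frame with `tree_id`, `date`, `hv_mm2_cm2`.
#' @export
start_of_day_hv <- function(hv, hour = 5, tol_min = 60) {
  assert_columns(hv, c("timestamp", "tree_id", "hv_mm2_cm2"), "Huber table")
  pieces <- lapply(split(hv, hv$tree_id), function(hi) {
    hi <- hi[order(hi$timestamp), ]
    dates <- unique(date_utc(hi$timestamp))
    target <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC") + hour * 3600
    idx <- nearest_index(target, hi$timestamp, tol_min * 60)
    data.frame(tree_id = hi$tree_id[1], date = dates,
               hv_mm2_cm2 = hi$hv_mm2_cm2[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
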