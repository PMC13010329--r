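# Orchestration: one reproducible run tying the stages together
# (simulate ->) fluxes -> carbon budget -> dendrometer growth -> summaries,
# with plain-CSV artifacts and a JSON manifest (config hash, seed, file
# checksums). Identical config + input => bit-identical artifacts.

#' Configure a pipeline run
#'
#' @param drought_start,recovery_start,experiment_end period boundary dates
#'   (`Date` or string). `NULL` means derive them from the scenario's
#'   embedded configuration (synthetic data carries its own timeline).
#' @param resample_interval common clock spacing for flux series (minutes).
#' @param gap_max longest gap interpolated across (minutes).
#' @param blank_tolerance blank-chamber matching window (minutes), about one
#'   multiplexer cycle.
#' @param min_valid_hours minimum joint valid hours for an unflagged
#'   carbon-budget day.
#' @param day_window,night_window gas-exchange averaging windows (hours,
#'   half-open).
#' @param growth_window daytime growth window (hours, half-open).
#' @param hv_rule sapwood proxy rule for [huber_series()].
#' @param tail_window terminal accumulation-rate window (days).
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the pipeline also simulates).
#' @return an object of class `run_config`.
#' @export
run_config <- function(drought_start = NULL, recovery_start = NULL,
                       experiment_end = NULL,
                       resample_interval = 60, gap_max = 180,
                       blank_tolerance = 90, min_valid_hours = 12,
                       day_window = c(9, 14), night_window = c(0, 5),
                       growth_window = c(5, 17),
                       hv_rule = c("running_max", "instantaneous"),
                       tail_window = 10, seed = 1L) {
  hv_rule <- match.arg(hv_rule)
  stopifnot(resample_interval > 0, gap_max > 0, blank_tolerance > 0,
            min_valid_hours > 0, tail_window >= 3)
  dates <- list(drought_start, recovery_start, experiment_end)
  if (!any(vapply(dates, is.null, logical(1)))) {
    dates <- lapply(dates, as.Date)
    if (!(dates[[1]] < dates[[2]] && dates[[2]] <= dates[[3]])) {
      stop("period dates must be ordered: drought_start < recovery_start <= experiment_end",
           call. = FALSE)
    }
  }
  structure(list(
    drought_start = drought_start, recovery_start = recovery_start,
    experiment_end = experiment_end,
    resample_interval = resample_interval, gap_max = gap_max,
    blank_tolerance = blank_tolerance, min_valid_hours = min_valid_hours,
    day_window = day_window, night_window = night_window,
    growth_window = growth_window, hv_rule = hv_rule,
    tail_window = tail_window, seed = as.integer(seed)
  ), class = "run_config")
}

pipeline_periods <- function(ds, config) {
  d0 <- config$drought_start
  r0 <- config$recovery_start
  e1 <- config$experiment_end
  if (is.null(d0) || is.null(r0) || is.null(e1)) {
    cc <- ds$config
    if (is.null(cc)) {
      stop("period dates missing: supply drought_start/recovery_start/experiment_end ",
           "or use a scenario that embeds its timeline", call. = FALSE)
    }
    d0 <- d0 %||% cc$start_date
    r0 <- r0 %||% (as.Date(cc$start_date) + cc$drought_days)
    e1 <- e1 %||% (as.Date(cc$start_date) + cc$drought_days + cc$recovery_days - 1)
  }
  d0 <- as.Date(d0)
  r0 <- as.Date(r0)
  e1 <- as.Date(e1)
  list(drought_start = d0, recovery_start = r0, experiment_end = e1,
       windows = list(drought = c(d0, r0 - 1),
                      recovery = c(r0, e1),
                      experimental = c(d0, e1)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes fluxes -> resampling -> daily/cumulative carbon -> period
#' summaries and tail rates -> basal area -> zero-growth -> daily growth
#' (with first-recovery-day masking) -> Huber values -> window summaries,
#' and (optionally) writes all artifacts plus a manifest to `out_dir`.
#'
#' @param input a `tree_scenario` (from [generate_scenario()] or
#'   [read_scenario()]) or a directory path of scenario CSV files.
#' @param config a [run_config()].
#' @param out_dir artifact directory; `NULL` to skip writing.
#' @return invisible list with `flux`, `daily_carbon`, `period_summary`,
#'   `tail_slopes`, `growth`, `daily_growth`, `huber`, `hv_start_of_day`,
#'   `summaries`, `periods`, `manifest`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  ds <- if (is.character(input)) read_scenario(input) else input
  stopifnot(inherits(ds, "tree_scenario"))
  per <- pipeline_periods(ds, config)

  flux <- compute_fluxes(ds$chamber, ds$trees, config$blank_tolerance)
  flux <- resample_cycle(flux, config$resample_interval, config$gap_max)

  daily <- daily_carbon(flux, config$min_valid_hours, config$resample_interval)
  daily <- cumulative_carbon(daily)
  psum <- period_summary(daily, per$windows, ds$trees)
  # short runs: fit over what exists, never beyond the series
  tw <- min(config$tail_window, min(table(daily$tree_id)))
  if (tw < 3) stop("need at least 3 days of data for tail accumulation rates",
                   call. = FALSE)
  tails <- tail_accumulation_rate(daily, tw)
  tails$treatment <- ds$trees$treatment[match(tails$tree_id, ds$trees$tree_id)]

  if (is.null(ds$dendro) || !nrow(ds$dendro)) {
    stop("configuration error: dendrometer records required but missing",
         call. = FALSE)
  }
  ba <- to_basal_area(ds$dendro, ds$trees)
  growth <- zero_growth(ba)
  dgrowth <- recovery_mask(daily_growth(growth), per$recovery_start)
  hv <- huber_series(ba, ds$trees, config$hv_rule)
  sod <- start_of_day_hv(hv, config$growth_window[1])

  # Treatment-level window summaries per period.
  shoot <- flux[flux$compartment == "shoot", ]
  vars <- list(gsw_daytime = list(shoot, "gsw_mmol_m2_s", config$day_window),
               anet_daytime = list(shoot, "anet_umol_m2_s", config$day_window),
               e_daytime = list(shoot, "e_mmol_m2_s", config$day_window),
               wuei_daytime = list(shoot, "wuei_umol_mol", config$day_window))
  sum_rows <- list()
  for (vn in names(vars)) {
    wm <- window_mean(vars[[vn]][[1]], vars[[vn]][[2]], vars[[vn]][[3]])
    for (pn in names(per$windows)) {
      win <- per$windows[[pn]]
      wp <- wm[wm$date >= win[1] & wm$date <= win[2], ]
      if (!nrow(wp)) next
      st <- treatment_stats(wp, ds$trees)
      st <- data.frame(variable = vn, st, period = pn, stringsAsFactors = FALSE)
      sum_rows[[length(sum_rows) + 1L]] <- st
    }
  }
  dg_ok <- dgrowth[!is.na(dgrowth$growth_mm2), ]
  names(dg_ok)[names(dg_ok) == "growth_mm2"] <- "value"
  for (pn in names(per$windows)) {
    win <- per$windows[[pn]]
    wp <- dg_ok[dg_ok$date >= win[1] & dg_ok$date <= win[2], ]
    if (!nrow(wp)) next
    st <- treatment_stats(wp, ds$trees)
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      variable = "growth_daily", st, period = pn, stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, sum_rows)
  summaries <- summaries[, c("variable", "treatment", "period", "mean", "se", "n")]

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("treeflux")),
    periods = lapply(per[c("drought_start", "recovery_start", "experiment_end")],
                     as.character),
    rows = list(chamber = nrow(ds$chamber), flux = nrow(flux),
                daily_carbon = nrow(daily), growth = nrow(growth)),
    masked_points = list(
      flux_co2 = sum(is.na(flux$f_co2_mol_s)),
      gsw = sum(is.na(flux$gsw_mmol_m2_s[flux$compartment == "shoot"])),
      flagged_days = sum(daily$flagged))
  )

  res <- list(flux = flux, daily_carbon = daily, period_summary = psum,
              tail_slopes = tails, growth = growth, daily_growth = dgrowth,
              huber = hv, hv_start_of_day = sod, summaries = summaries,
              periods = per, manifest = manifest)

  if (!is.null(out_dir)) {
    ok <- FALSE
    on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    wr <- function(df, name) {
      if ("timestamp" %in% names(df)) df$timestamp <- format_time(df$timestamp)
      for (cc in names(df)) if (inherits(df[[cc]], "Date")) df[[cc]] <- as.character(df[[cc]])
      write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
    }
    wr(flux, "flux.csv")
    wr(daily, "daily_carbon.csv")
    wr(psum, "period_summary.csv")
    wr(tails, "tail_slopes.csv")
    wr(growth[, c("timestamp", "tree_id", "basal_area_mm2",
                  "growth_cum_mm2", "twd_mm2")], "growth.csv")
    wr(dgrowth, "daily_growth.csv")
    wr(hv, "huber.csv")
    wr(sod, "hv_start_of_day.csv")
    wr(summaries, "summaries.csv")
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$files <- as.list(tools::md5sum(files))
    names(manifest$files) <- basename(files)
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
  }
  invisible(res)
}

#' Validate a scenario input directory
#'
#' Schema and plausibility checks: required files and columns, positive
#' flow, CO2 mole fractions in a plausible greenhouse range (300-1000 ppm),
#' humidity within physical bounds, strictly increasing timestamps per
#' series, positive leaf areas and diameters. Returns a machine-readable
#' issue table; zero rows means a valid directory.
#'
#' @param directory scenario directory as written by [write_scenario()].
#' @return data.frame with `file`, `severity` (`error`/`warning`), `issue`,
#'   `detail`.
#' @export
validate_inputs <- function(directory) {
  issues <- list()
  add <- function(file, severity, issue, detail = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, severity = severity, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  need <- c("chamber.csv", "dendro.csv", "trees.csv", "soil.csv")
  for (f in need) {
    if (!file.exists(file.path(directory, f))) add(f, "error", "missing file")
  }
  if (length(issues)) return(do.call(rbind, issues))

  ch <- read.csv(file.path(directory, "chamber.csv"), stringsAsFactors = FALSE)
  ch_cols <- c("timestamp", "tree_id", "compartment", "c_ref_ppm",
               "c_sample_ppm", "w_ref_mmol", "w_sample_mmol", "flow_mol_s",
               "t_air_c", "p_kpa")
  miss <- setdiff(ch_cols, names(ch))
  if (length(miss)) {
    add("chamber.csv", "error", "missing columns", paste(miss, collapse = ", "))
  } else {
    bad <- which(ch$flow_mol_s <= 0)
    if (length(bad)) add("chamber.csv", "error", "non-positive flow",
                         paste("rows", paste(utils::head(bad, 5), collapse = ",")))
    bad <- which(ch$c_sample_ppm < 300 | ch$c_sample_ppm > 1000 |
                   ch$c_ref_ppm < 300 | ch$c_ref_ppm > 1000)
    if (length(bad)) add("chamber.csv", "warning", "CO2 outside 300-1000 ppm",
                         paste("rows", paste(utils::head(bad, 5), collapse = ",")))
    bad <- which(ch$w_sample_mmol < 0 | ch$w_sample_mmol >= 1000 |
                   ch$w_ref_mmol < 0 | ch$w_ref_mmol >= 1000)
    if (length(bad)) add("chamber.csv", "error", "humidity outside [0, 1000)",
                         paste("rows", paste(utils::head(bad, 5), collapse = ",")))
    ts <- parse_time(ch$timestamp)
    for (key in unique(paste(ch$tree_id, ch$compartment))) {
      sel <- paste(ch$tree_id, ch$compartment) == key
      if (is.unsorted(ts[sel], strictly = TRUE)) {
        add("chamber.csv", "error", "timestamps not strictly increasing", key)
      }
    }
    if (!all(ch$compartment %in% c("shoot", "root", "blank"))) {
      add("chamber.csv", "error", "unknown compartment",
          paste(setdiff(unique(ch$compartment), c("shoot", "root", "blank")),
                collapse = ", "))
    }
  }

  tr <- read.csv(file.path(directory, "trees.csv"), stringsAsFactors = FALSE)
  if (!all(c("tree_id", "treatment", "leaf_area_m2", "initial_diameter_mm")
           %in% names(tr))) {
    add("trees.csv", "error", "missing columns")
  } else {
    if (any(tr$leaf_area_m2 <= 0)) add("trees.csv", "error", "non-positive leaf area")
    if (any(tr$initial_diameter_mm <= 0)) add("trees.csv", "error", "non-positive diameter")
    if (!all(tr$treatment %in% c("control", "mild", "severe"))) {
      add("trees.csv", "error", "unknown treatment name",
          paste(setdiff(unique(tr$treatment), c("control", "mild", "severe")),
                collapse = ", "))
    }
  }

  dn <- read.csv(file.path(directory, "dendro.csv"), stringsAsFactors = FALSE)
  if (!all(c("timestamp", "tree_id", "displacement_um") %in% names(dn))) {
    add("dendro.csv", "error", "missing columns")
  } else {
    ts <- parse_time(dn$timestamp)
    for (id in unique(dn$tree_id)) {
      if (is.unsorted(ts[dn$tree_id == id], strictly = TRUE)) {
        add("dendro.csv", "error", "timestamps not strictly increasing", id)
      }
    }
  }

  if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(), severity = character(),
               issue = character(), detail = character())
}
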