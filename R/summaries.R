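# Window-based aggregation and treatment-level descriptive statistics.
# Convention: time windows are half-open [start, end) hours on the resampled
# clock, avoiding double counting at boundaries; treatment statistics always
# average within an individual first, then across individuals.

#' Per-tree daily mean of a variable inside an hour window
#'
#' Arithmetic mean of valid points whose hour of day falls in
#' `[window[1], window[2])`, per tree and UTC day; missing when no valid
#' point falls inside the window.
#'
#' @param x long table with `timestamp`, `tree_id`, and the value column.
#' @param value name of the value column.
#' @param window `c(start_hour, end_hour)`, half-open, within 0-24.
#' @return data.frame with `tree_id`, `date`, `value`.
#' @examples
#' # daytime gas-exchange window 09:00-14:00, nighttime 00:00-05:00
#' @export
window_mean <- function(x, value, window = c(9, 14)) {
  assert_columns(x, c("timestamp", "tree_id", value), "series table")
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= 24)
  t <- parse_time(x$timestamp)
  h <- hour_of_day(t)
  keep <- h >= window[1] & h < window[2]
  xi <- data.frame(tree_id = x$tree_id[keep], date = date_utc(t[keep]),
                   v = x[[value]][keep], stringsAsFactors = FALSE)
  s <- tapply(xi$v, paste(xi$tree_id, xi$date, sep = "\r"),
              function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  if (!length(s)) {
    return(data.frame(tree_id = character(), date = as.Date(character()),
                      value = numeric()))
  }
  parts <- strsplit(names(s), "\r", fixed = TRUE)
  out <- data.frame(tree_id = vapply(parts, `[`, "", 1),
                    date = as.Date(vapply(parts, `[`, "", 2)),
                    value = as.numeric(s), stringsAsFactors = FALSE)
  out <- out[order(out$tree_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Treatment mean and standard error with per-individual-first averaging
#'
#' Collapses possibly repeated per-tree values to one mean per tree (and per
#' optional group), then reports the across-tree mean, standard error
#' (sd/sqrt(n)) and n per treatment. The SE of a single-tree group is
#' missing, identical trees give SE 0, and permuting within-tree sample
#' order never changes the result.
#'
#' @param x table with `tree_id` and the value column; may hold repeated
#'   measurements per tree.
#' @param trees tree metadata with `tree_id` and `treatment`.
#' @param value name of the value column (default `"value"`).
#' @param group optional name of an additional grouping column (e.g. a
#'   period or timepoint).
#' @return data.frame with `treatment`, optional group column, `mean`, `se`,
#'   `n`.
#' @export
treatment_stats <- function(x, trees, value = "value", group = NULL) {
  assert_columns(x, c("tree_id", value, group), "values table")
  assert_columns(trees, c("tree_id", "treatment"), "trees table")
  g <- if (is.null(group)) rep("", nrow(x)) else as.character(x[[group]])
  per_tree <- tapply(x[[value]], paste(x$tree_id, g, sep = "\r"),
                     mean, na.rm = TRUE)
  parts <- strsplit(names(per_tree), "\r", fixed = TRUE)
  pt <- data.frame(tree_id = vapply(parts, `[`, "", 1),
                   g = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
                   value = as.numeric(per_tree), stringsAsFactors = FALSE)
  pt$treatment <- trees$treatment[match(pt$tree_id, trees$tree_id)]
  if (anyNA(pt$treatment)) {
    stop("values reference trees absent from the metadata", call. = FALSE)
  }
  out <- list()
  for (key in unique(paste(pt$treatment, pt$g, sep = "\r"))) {
    sel <- paste(pt$treatment, pt$g, sep = "\r") == key
    v <- pt$value[sel]
    v <- v[!is.na(v)]
    kk <- strsplit(key, "\r", fixed = TRUE)[[1]]
    row <- data.frame(treatment = kk[1], mean = mean(v), se = se_of_mean(v),
                      n = length(v), stringsAsFactors = FALSE)
    if (!is.null(group)) row[[group]] <- if (length(kk) > 1) kk[2] else ""
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  if (!is.null(group)) out <- out[, c("treatment", group, "mean", "se", "n")]
  rownames(out) <- NULL
  out
}

#' Percent difference of a treatment mean from the control mean
#'
#' `100 * (treatment - control) / |control|`; errors when the control mean
#' is zero.
#'
#' @param treatment_mean,control_mean scalar means.
#' @return signed percent difference.
#' @examples
#' percent_difference(45.02, 236.9) # about -81
#' @export
percent_difference <- function(treatment_mean, control_mean) {
  if (any(control_mean == 0)) {
    stop("control mean is zero; percent difference undefined", call. = FALSE)
  }
  100 * (treatment_mean - control_mean) / abs(control_mean)
}

#' Ordinary least-squares slope with standard error
#'
#' Shared utility behind the terminal carbon-accumulation and diurnal
#' growth-rate fits.
#'
#' @param x,y numeric vectors, `length >= 3` after removing missing pairs.
#' @return named numeric vector `c(slope = , se = )`.
#' @export
ols_slope <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points for an OLS slope", call. = FALSE)
  fit <- lm(y ~ x)
  # classical slope SE; computed directly so an exactly collinear fit
  # reports SE 0 without complaint
  r <- stats::residuals(fit)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(r^2) / (length(x) - 2)) / sqrt(sxx)
  c(slope = unname(coef(fit)[2]), se = se)
}
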