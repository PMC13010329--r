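# Internal helpers shared across modules. All timestamps are handled in UTC;
# day boundaries fall at UTC midnight so the 00:00-05:00 nighttime window is
# well defined regardless of host timezone.

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", x, fixed = TRUE)
  x <- gsub("Z", "", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC")
  if (anyNA(out) && !all(is.na(x))) {
    stop("unparseable timestamps; expected ISO-8601", call. = FALSE)
  }
  out
}

format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

date_utc <- function(t) as.Date(t, tz = "UTC")

se_of_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation streams never perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic string hash (polynomial, mod a prime below 2^31); used to
# expand one global seed into independent per-stream child seeds so that
# adding a tree or channel never perturbs existing streams.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  h
}

stream_seed <- function(seed, stream) {
  as.integer((seed + 1000003 * (stable_hash(stream) %% 2000003)) %% 2147483647)
}

# Nearest-neighbour index of each `query` time in sorted `ref` times, NA when
# further than `tol` seconds.
nearest_index <- function(query, ref, tol) {
  if (length(ref) == 0L) return(rep(NA_integer_, length(query)))
  q <- as.numeric(query)
  r <- as.numeric(ref)
  i <- findInterval(q, r)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(r))
  dlo <- abs(q - r[lo])
  dhi <- abs(q - r[hi])
  idx <- ifelse(dhi < dlo, hi, lo)
  d <- pmin(dlo, dhi)
  idx[d > tol] <- NA_integer_
  as.integer(idx)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
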