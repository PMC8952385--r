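# Internal helpers shared across modules.

# Signal a classed condition so callers can dispatch on failure modes.
stop_pr <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(paste0("peakrescue_", class), "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Trapezoidal integral of y(x); x must be sorted increasing.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

ppm_diff <- function(a, b) abs(a - b) / ((a + b) / 2) * 1e6

# Canonical (possibly empty) feature table. All tiers emit this shape.
feature_columns <- c(
  "feature_id", "mz", "rt", "rtmin", "rtmax",
  "intensity", "area", "source", "ms2_scan", "sn"
)

#' Canonical feature tables
#'
#' `empty_features()` returns a zero-row feature table in the canonical
#' column layout; `as_features()` coerces any data.frame with at least
#' `mz`, `rt` and `intensity` columns into it, filling defaults for the
#' rest.
#'
#' @return a feature `data.frame` with columns `feature_id, mz, rt, rtmin,
#'   rtmax, intensity, area, source, ms2_scan, sn`.
#' @export
empty_features <- function() {
  data.frame(
    feature_id = character(0), mz = numeric(0), rt = numeric(0),
    rtmin = numeric(0), rtmax = numeric(0), intensity = numeric(0),
    area = numeric(0), source = character(0), ms2_scan = integer(0),
    sn = numeric(0), stringsAsFactors = FALSE
  )
}

#' @param df data.frame to coerce.
#' @param source default source tag for rows without one.
#' @rdname empty_features
#' @export
as_features <- function(df, source = "PP") {
  out <- empty_features()
  if (nrow(df) == 0L) return(out)
  n <- nrow(df)
  get <- function(col, default) if (col %in% names(df)) df[[col]] else rep(default, n)
  out <- data.frame(
    feature_id = as.character(get("feature_id", NA_character_)),
    mz = as.numeric(df$mz), rt = as.numeric(df$rt),
    rtmin = as.numeric(get("rtmin", NA_real_)),
    rtmax = as.numeric(get("rtmax", NA_real_)),
    intensity = as.numeric(df$intensity),
    area = as.numeric(get("area", NA_real_)),
    source = as.character(get("source", source)),
    ms2_scan = as.integer(get("ms2_scan", NA_integer_)),
    sn = as.numeric(get("sn", NA_real_)),
    stringsAsFactors = FALSE
  )
  miss <- is.na(out$feature_id)
  if (any(miss)) out$feature_id[miss] <- sprintf("F%04d", which(miss))
  if (anyNA(out$rtmin)) out$rtmin[is.na(out$rtmin)] <- out$rt[is.na(out$rtmin)]
  if (anyNA(out$rtmax)) out$rtmax[is.na(out$rtmax)] <- out$rt[is.na(out$rtmax)]
  out
}

order_features <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$mz, df$rt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Largest run of consecutive TRUE containing position `at` (indices lo:hi).
run_around <- function(flags, at) {
  if (!isTRUE(flags[at])) return(c(at, at - 1L)) # empty run
  lo <- at
  while (lo > 1L && flags[lo - 1L]) lo <- lo - 1L
  hi <- at
  while (hi < length(flags) && flags[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}
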