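#' Read an MSP spectral library
#'
#' Parses the plain-text MSP dialect used by public MS2 libraries
#' (MassBank/MS-DIAL style): records start at a `Name:` line, carry a
#' precursor m/z (`PRECURSORMZ:` / `PrecursorMZ:`), a `Num Peaks:` count and
#' one fragment `m/z intensity` pair per line. Records lacking a precursor
#' m/z or fragments are skipped; the number skipped is reported with a
#' message.
#'
#' @param path path to an MSP file.
#' @return a list of library entries, each a list with `compound_name`,
#'   `precursor_mz`, `adduct`, `fragments` (two-column matrix `mz`,
#'   `intensity`) and `ids` (semicolon-joined external identifier strings,
#'   uninterpreted).
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop_pr(paste0("file not found: ", path), "format")
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^name\\s*:", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop_pr("no parseable MSP record (no 'Name:' line)", "format")
  bounds <- c(starts, length(lines) + 1L)
  entries <- list()
  skipped <- 0L
  for (k in seq_along(starts)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    header <- grep("^[A-Za-z][^:]*:", block, value = TRUE)
    key <- toupper(trimws(sub(":.*$", "", header)))
    val <- trimws(sub("^[^:]*:", "", header))
    name <- val[match("NAME", key)]
    prec <- suppressWarnings(as.numeric(val[match("PRECURSORMZ", key)]))
    adduct <- val[match(TRUE, key %in% c("PRECURSORTYPE", "ADDUCT"))]
    id_keys <- key %in% c("HMDB", "KEGG", "INCHIKEY", "DB#", "CASNO", "ID")
    ids <- if (any(id_keys)) paste(paste0(key[id_keys], ":", val[id_keys]), collapse = ";") else NA_character_
    peak_lines <- grep("^\\s*[0-9]", block, value = TRUE)
    frag <- NULL
    if (length(peak_lines)) {
      parts <- strsplit(trimws(peak_lines), "[\\s;,\t]+", perl = TRUE)
      ok <- lengths(parts) >= 2L
      if (any(ok)) {
        frag <- do.call(rbind, lapply(parts[ok], function(p)
          suppressWarnings(as.numeric(p[1:2]))))
        frag <- frag[stats::complete.cases(frag) & frag[, 1] > 0, , drop = FALSE]
        colnames(frag) <- c("mz", "intensity")
      }
    }
    if (is.na(prec) || is.null(frag) || nrow(frag) == 0L) {
      skipped <- skipped + 1L
      next
    }
    entries[[length(entries) + 1L]] <- list(
      compound_name = name, precursor_mz = prec,
      adduct = if (is.na(adduct)) NA_character_ else adduct,
      fragments = frag, ids = ids
    )
  }
  if (skipped > 0L)
    message(sprintf("read_msp: skipped %d record(s) without precursor m/z or peaks", skipped))
  if (length(entries) == 0L) stop_pr("no usable MSP record in file", "format")
  entries
}

#' Read and write feature tables
#'
#' The CSV dialect is
#' `feature_id,mz,rt,rtmin,rtmax,intensity,area,source,ms2_scan,sn`; only
#' `mz`, `rt` and `intensity` are mandatory on read. Externally produced
#' tables are treated as the peak-picking tier (`source = "PP"`), so the
#' rescue tiers can extend them.
#'
#' @param path CSV path.
#' @return a canonical feature `data.frame`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_pr(paste0("file not found: ", path), "format")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "rt", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_pr(paste0("feature table missing column(s): ", paste(miss, collapse = ", ")), "schema")
  as_features(df, source = "PP")
}

#' @param features canonical feature `data.frame`.
#' @rdname read_feature_table
#' @export
write_feature_table <- function(features, path) {
  features <- as_features(features)
  write.csv(features[, feature_columns], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a targeted compound list
#'
#' CSV with columns `name,mz,rt` (RT in seconds).
#'
#' @param path CSV path.
#' @return a `data.frame` with columns `name`, `mz`, `rt`.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop_pr(paste0("file not found: ", path), "format")
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "mz", "rt"), names(df))
  if (length(miss))
    stop_pr(paste0("targeted list missing column(s): ", paste(miss, collapse = ", ")), "schema")
  if (any(df$mz <= 0) || any(df$rt < 0))
    stop_pr("targeted list requires mz > 0 and rt >= 0", "schema")
  df[, c("name", "mz", "rt")]
}

#' Write the aligned group table
#'
#' One row per feature group: `group_id,mz_med,rt_med,source_summary`, one
#' intensity column per sample, and a `filled_flags` column marking which
#' samples were gap-filled (semicolon-joined sample ids).
#'
#' @param groups result of [group_features()] / [gap_fill()].
#' @param path CSV path.
#' @export
write_aligned_table <- function(groups, path) {
  write.csv(aligned_table(groups), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
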