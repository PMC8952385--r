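#' Annotation configuration
#'
#' @param precursor_tol precursor m/z match tolerance (Th).
#' @param fragment_tol fragment m/z match tolerance (Th).
#' @param score_threshold minimum dot-product score reported.
#' @param intensity_power exponent applied to fragment intensities before
#'   scoring (0.5 = square-root weighting, the common metabolomics choice).
#' @param mz_power exponent applied to fragment m/z (0 = no m/z weighting).
#' @return an `annotation_config` list.
#' @export
annotation_config <- function(precursor_tol = 0.01, fragment_tol = 0.02,
                              score_threshold = 0.7, intensity_power = 0.5,
                              mz_power = 0) {
  stopifnot(precursor_tol > 0, fragment_tol > 0,
            score_threshold >= 0, score_threshold <= 1)
  structure(as.list(environment()), class = "annotation_config")
}

#' Spectral dot-product similarity
#'
#' Fragments of the two spectra are matched greedily by nearest m/z within
#' `fragment_tol` (each fragment used at most once; ties broken toward the
#' higher intensity product). With weights
#' `w = intensity^intensity_power * mz^mz_power`, the score is
#' `(sum over matched pairs of w_a * w_b)^2 / (sum(w_a^2) * sum(w_b^2))`,
#' the sums in the denominator running over all fragments of both spectra.
#' The score is symmetric and lies in `[0, 1]`, reaching 1 only for
#' proportional, fully matched spectra.
#'
#' @param spec_a,spec_b two-column matrices (or data.frames) `mz`,
#'   `intensity`.
#' @param cfg an [annotation_config()].
#' @return similarity score in `[0, 1]`.
#' @export
dot_product <- function(spec_a, spec_b, cfg = annotation_config()) {
  a <- as.matrix(spec_a); b <- as.matrix(spec_b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop_pr("dot product undefined for an empty spectrum", "empty_spectrum")
  wa <- a[, 2]^cfg$intensity_power * a[, 1]^cfg$mz_power
  wb <- b[, 2]^cfg$intensity_power * b[, 1]^cfg$mz_power
  pairs <- greedy_fragment_match(a[, 1], b[, 1], wa, wb, cfg$fragment_tol)
  num <- if (nrow(pairs)) sum(wa[pairs[, 1]] * wb[pairs[, 2]]) else 0
  den <- sum(wa^2) * sum(wb^2)
  if (den <= 0) return(0)
  min(1, num^2 / den)
}

# Greedy one-to-one matching of fragments by nearest m/z within tol.
greedy_fragment_match <- function(mza, mzb, wa, wb, tol) {
  cand <- which(outer(mza, mzb, function(x, y) abs(x - y)) <= tol, arr.ind = TRUE)
  if (length(cand) == 0L) return(matrix(integer(0), 0, 2))
  d <- abs(mza[cand[, 1]] - mzb[cand[, 2]])
  prod <- wa[cand[, 1]] * wb[cand[, 2]]
  cand <- cand[order(d, -prod), , drop = FALSE]
  ua <- logical(length(mza)); ub <- logical(length(mzb))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!ua[cand[i, 1]] && !ub[cand[i, 2]]) {
      ua[cand[i, 1]] <- TRUE; ub[cand[i, 2]] <- TRUE; keep[i] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Annotate features against an MS2 spectral library
#'
#' For each feature carrying an MS2 scan, library entries whose precursor
#' m/z lies within `precursor_tol` of the feature m/z are scored with
#' [dot_product()]; hits at or above `score_threshold` are reported sorted
#' by score (rank 1 = top hit). Features without an attached MS2 scan, or
#' whose MS2 spectrum is empty, are skipped (counted in attribute
#' `skipped`).
#'
#' @param features feature data.frame with `ms2_scan`.
#' @param run the `ms_run` the features came from.
#' @param library list of library entries from [read_msp()].
#' @param cfg an [annotation_config()].
#' @return data.frame `feature_id,compound_name,score,precursor_delta_mz,`
#'   `library_ids,rank`.
#' @export
annotate_features <- function(features, run, library, cfg = annotation_config()) {
  if (length(library) == 0L) stop_pr("spectral library is empty", "config")
  lib_mz <- vapply(library, `[[`, numeric(1), "precursor_mz")
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(features))) {
    scan <- features$ms2_scan[i]
    if (is.na(scan)) next
    sp <- run$spectra[[scan + 1L]]
    if (length(sp$mz) == 0L) { skipped <- skipped + 1L; next }
    exp_spec <- cbind(mz = sp$mz, intensity = sp$intensity)
    hits <- which(abs(lib_mz - features$mz[i]) <= cfg$precursor_tol)
    if (length(hits) == 0L) next
    sc <- vapply(hits, function(h)
      dot_product(exp_spec, library[[h]]$fragments, cfg), numeric(1))
    ok <- sc >= cfg$score_threshold
    if (!any(ok)) next
    hits <- hits[ok]; sc <- sc[ok]
    ord <- order(-sc)
    out[[length(out) + 1L]] <- data.frame(
      feature_id = features$feature_id[i],
      compound_name = vapply(library[hits[ord]], `[[`, character(1), "compound_name"),
      score = sc[ord],
      precursor_delta_mz = lib_mz[hits[ord]] - features$mz[i],
      library_ids = vapply(library[hits[ord]], function(e)
        if (is.na(e$ids)) "" else e$ids, character(1)),
      rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    feature_id = character(0), compound_name = character(0),
    score = numeric(0), precursor_delta_mz = numeric(0),
    library_ids = character(0), rank = integer(0)
  )
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
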