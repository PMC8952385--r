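#' MS2-rescue configuration
#'
#' Defaults: precursors deduplicated within 0.01 Th and 30 s; candidate
#' features confirmed in the raw data within 0.01 Th and 60 s; a valid
#' rescued feature must exceed 3x the local noise and appear in at least 4
#' consecutive MS1 scans.
#'
#' @param dedup_mz_tol,dedup_rt_tol precursor deduplication window (Th, s).
#' @param find_ppm_tol ppm tolerance for locating the precursor among MS1
#'   centroids (e.g. when back-filling missing precursor intensities).
#' @param confirm_mass_tol,confirm_rt_tol window (Th, s) for confirming a
#'   candidate in the raw data (EIC extraction, novelty check).
#' @param noise_fold required apex-to-local-noise ratio.
#' @param min_consecutive_scans minimum consecutive MS1 scans with signal.
#' @param noise_floor fallback noise level (counts) when too few EIC points
#'   are available for estimation.
#' @return an `mr_config` list.
#' @export
mr_config <- function(dedup_mz_tol = 0.01, dedup_rt_tol = 30,
                      find_ppm_tol = 10, confirm_mass_tol = 0.01,
                      confirm_rt_tol = 60, noise_fold = 3,
                      min_consecutive_scans = 4, noise_floor = 100) {
  stopifnot(dedup_mz_tol > 0, dedup_rt_tol > 0, find_ppm_tol > 0,
            confirm_mass_tol > 0, confirm_rt_tol > 0, noise_fold > 0,
            min_consecutive_scans > 0, noise_floor > 0)
  structure(as.list(environment()), class = "mr_config")
}

#' Deduplicate MS2 precursors
#'
#' Collects every MS2 precursor in the run and clusters them greedily in
#' descending precursor-intensity order: any precursor within
#' `dedup_mz_tol` AND `dedup_rt_tol` of an already-kept one is absorbed, so
#' only the most intense trigger of each ion survives.
#'
#' @param run an `ms_run`.
#' @param cfg an [mr_config()].
#' @return data.frame of candidates (`mz`, `rt`, `intensity`, `ms2_scan`),
#'   sorted by (mz, rt). Empty if the run has no MS2 scans.
#' @export
dedupe_precursors <- function(run, cfg = mr_config()) {
  idx <- ms2_scans(run)
  empty <- data.frame(mz = numeric(0), rt = numeric(0),
                      intensity = numeric(0), ms2_scan = integer(0))
  if (length(idx) == 0L) return(empty)
  sp <- run$spectra[idx + 1L]
  cand <- data.frame(
    mz = vapply(sp, function(s) s$precursor_mz, numeric(1)),
    rt = vapply(sp, function(s) s$rt, numeric(1)),
    intensity = vapply(sp, function(s) {
      v <- s$precursor_intensity
      if (is.null(v) || is.na(v)) 0 else v
    }, numeric(1)),
    ms2_scan = idx
  )
  cand <- cand[order(-cand$intensity, cand$mz, cand$rt), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept)) {
      absorbed <- any(abs(cand$mz[kept] - cand$mz[i]) <= cfg$dedup_mz_tol &
                      abs(cand$rt[kept] - cand$rt[i]) <= cfg$dedup_rt_tol)
      if (absorbed) next
    }
    kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$mz, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop precursor candidates already explained by picked features
#'
#' A candidate within `confirm_mass_tol` of a picked feature's m/z AND
#' within `confirm_rt_tol` of its RT has already been extracted and is
#' removed; order is preserved.
#'
#' @param candidates data.frame from [dedupe_precursors()].
#' @param picked feature data.frame (the PP tier).
#' @param cfg an [mr_config()].
#' @export
filter_novel <- function(candidates, picked, cfg = mr_config()) {
  if (nrow(candidates) == 0L || is.null(picked) || nrow(picked) == 0L)
    return(candidates)
  drop <- vapply(seq_len(nrow(candidates)), function(i) {
    any(abs(picked$mz - candidates$mz[i]) <= cfg$confirm_mass_tol &
        abs(picked$rt - candidates$rt[i]) <= cfg$confirm_rt_tol)
  }, logical(1))
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract an ion chromatogram
#'
#' One point per MS1 scan with RT in `[rt_center - rt_tol, rt_center +
#' rt_tol]`; the per-scan intensity is the maximum centroid intensity within
#' the closed m/z window `[mz - mass_tol, mz + mass_tol]` (0 if none). The
#' `mz` column carries the m/z of that maximal centroid (`NA` when the scan
#' has no matching centroid).
#'
#' @param run an `ms_run`.
#' @param mz,mass_tol target m/z and half-window (Th).
#' @param rt_center,rt_tol RT window center and half-width (seconds).
#' @return data.frame `scan_index`, `rt`, `intensity`, `mz` in RT order;
#'   zero rows when no MS1 scan falls in the window.
#' @export
extract_eic <- function(run, mz, mass_tol, rt_center, rt_tol) {
  stopifnot(mass_tol > 0)
  rts <- ms1_rts(run)
  sel <- which(rts >= rt_center - rt_tol & rts <= rt_center + rt_tol)
  out <- data.frame(scan_index = integer(0), rt = numeric(0),
                    intensity = numeric(0), mz = numeric(0))
  if (length(sel) == 0L) return(out)
  lo <- mz - mass_tol; hi <- mz + mass_tol
  n <- length(sel)
  ints <- numeric(n); mzs <- rep(NA_real_, n); sidx <- integer(n)
  for (k in seq_len(n)) {
    sp <- run$spectra[[run$ms1_index[sel[k]] + 1L]]
    sidx[k] <- sp$scan_index
    i1 <- findInterval(lo, sp$mz) + 1L
    i2 <- findInterval(hi, sp$mz)
    if (i2 >= i1) {
      seg <- i1:i2
      w <- seg[which.max(sp$intensity[seg])]
      ints[k] <- sp$intensity[w]
      mzs[k] <- sp$mz[w]
    }
  }
  data.frame(scan_index = sidx, rt = rts[sel], intensity = ints, mz = mzs)
}

#' Relocate a precursor candidate to its chromatographic apex
#'
#' DDA triggers usually fire on a peak flank; the candidate's RT and
#' intensity are replaced by the maximum-intensity point of its EIC (ties
#' broken toward the original trigger RT).
#'
#' @param run an `ms_run`.
#' @param cand one-row candidate data.frame (`mz`, `rt`, `intensity`,
#'   `ms2_scan`).
#' @param cfg an [mr_config()].
#' @return the candidate with updated `rt`/`intensity` plus `apex_scan`
#'   (scan_index of the apex MS1 scan).
#' @export
relocate_to_apex <- function(run, cand, cfg = mr_config()) {
  eic <- extract_eic(run, cand$mz, cfg$confirm_mass_tol, cand$rt, cfg$confirm_rt_tol)
  if (nrow(eic) == 0L || all(eic$intensity <= 0))
    stop_pr("no signal in EIC window; apex not found", "apex_not_found")
  mx <- max(eic$intensity)
  at <- which(eic$intensity == mx)
  at <- at[which.min(abs(eic$rt[at] - cand$rt))]
  cand$rt <- eic$rt[at]
  cand$intensity <- eic$intensity[at]
  cand$apex_scan <- eic$scan_index[at]
  cand
}

#' Estimate local noise from an EIC
#'
#' Median of the nonzero EIC intensities outside the excluded RT interval;
#' falls back to `floor` when fewer than 4 such points exist. The returned
#' value is never below 1.
#'
#' @param eic data.frame from [extract_eic()].
#' @param exclude_rt length-2 numeric, RT interval (the peak) to exclude.
#' @param floor fallback noise level (counts).
#' @export
estimate_local_noise <- function(eic, exclude_rt, floor = 100) {
  vals <- eic$intensity[eic$intensity > 0 &
                        (eic$rt < exclude_rt[1] | eic$rt > exclude_rt[2])]
  if (length(vals) < 4L) return(max(floor, 1))
  max(median(vals), 1)
}

#' Validate an apex-relocated candidate as a rescued feature
#'
#' A candidate is valid iff its apex intensity exceeds `noise_fold` times
#' the local noise AND its EIC shows at least `min_consecutive_scans`
#' consecutive MS1 scans with nonzero intensity in the stretch containing
#' the apex. The rescued feature spans that stretch; its area is the
#' trapezoidal integral over it.
#'
#' @param run an `ms_run`.
#' @param cand apex-relocated candidate (see [relocate_to_apex()]).
#' @param cfg an [mr_config()].
#' @return a list with `valid` (logical); when valid, `feature` (one-row
#'   feature data.frame, source `"MR"`); otherwise `reason`
#'   (`"noise_fail"` or `"consecutive_fail"`).
#' @export
validate_feature <- function(run, cand, cfg = mr_config()) {
  eic <- extract_eic(run, cand$mz, cfg$confirm_mass_tol, cand$rt, cfg$confirm_rt_tol)
  at <- which(eic$scan_index == cand$apex_scan)
  if (length(at) != 1L) at <- which.max(eic$intensity)
  rr <- run_around(eic$intensity > 0, at)
  n_consec <- rr[2] - rr[1] + 1L
  noise <- estimate_local_noise(eic, c(eic$rt[rr[1]], eic$rt[rr[2]]),
                                floor = cfg$noise_floor)
  if (!(cand$intensity > cfg$noise_fold * noise))
    return(list(valid = FALSE, reason = "noise_fail", noise = noise))
  if (n_consec < cfg$min_consecutive_scans)
    return(list(valid = FALSE, reason = "consecutive_fail", noise = noise))
  seg <- rr[1]:rr[2]
  wts <- eic$intensity[seg]
  mzv <- eic$mz[seg]
  okm <- !is.na(mzv) & wts > 0
  mz_out <- if (any(okm)) sum(mzv[okm] * wts[okm]) / sum(wts[okm]) else cand$mz
  feat <- data.frame(
    feature_id = NA_character_, mz = mz_out, rt = cand$rt,
    rtmin = eic$rt[rr[1]], rtmax = eic$rt[rr[2]],
    intensity = cand$intensity, area = trapz(eic$rt[seg], wts),
    source = "MR", ms2_scan = as.integer(cand$ms2_scan),
    sn = cand$intensity / noise, stringsAsFactors = FALSE
  )
  list(valid = TRUE, feature = feat, noise = noise)
}

#' Rescue features from their MS2 precursors (the MR tier)
#'
#' Pipeline: deduplicate precursors, drop those already picked, relocate
#' each survivor to its EIC apex, then validate against the local noise and
#' consecutive-scan rules. Stage counts and per-candidate rejection reasons
#' are attached as attributes `log` and `rejections`.
#'
#' @param run an `ms_run`.
#' @param picked feature data.frame from the PP tier (may be empty).
#' @param cfg an [mr_config()].
#' @return feature data.frame (source `"MR"`), sorted by (mz, rt).
#' @export
run_mr <- function(run, picked = empty_features(), cfg = mr_config()) {
  cand <- dedupe_precursors(run, cfg)
  novel <- filter_novel(cand, picked, cfg)
  feats <- list()
  rej <- list()
  for (i in seq_len(nrow(novel))) {
    ci <- novel[i, , drop = FALSE]
    ci <- tryCatch(relocate_to_apex(run, ci, cfg), error = function(e) NULL)
    if (is.null(ci)) {
      rej[[length(rej) + 1L]] <- data.frame(mz = novel$mz[i], rt = novel$rt[i],
                                            reason = "apex_not_found")
      next
    }
    v <- validate_feature(run, ci, cfg)
    if (!v$valid) {
      rej[[length(rej) + 1L]] <- data.frame(mz = ci$mz, rt = ci$rt, reason = v$reason)
      next
    }
    # the relocated (putative) feature must still be novel: relocation can
    # move the RT by up to confirm_rt_tol
    if (nrow(picked) > 0L &&
        any(abs(picked$mz - v$feature$mz) <= cfg$confirm_mass_tol &
            abs(picked$rt - v$feature$rt) <= cfg$confirm_rt_tol)) {
      rej[[length(rej) + 1L]] <- data.frame(mz = ci$mz, rt = ci$rt,
                                            reason = "already_extracted")
      next
    }
    feats[[length(feats) + 1L]] <- v$feature
  }
  out <- if (length(feats)) do.call(rbind, feats) else empty_features()
  if (nrow(out) > 1L) {
    # distinct triggers can relocate onto the same apex; keep the stronger
    out <- out[order(-out$intensity), , drop = FALSE]
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      kept <- which(keep)
      keep[i] <- !length(kept) ||
        !any(abs(out$mz[kept] - out$mz[i]) <= cfg$dedup_mz_tol &
             abs(out$rt[kept] - out$rt[i]) <= cfg$dedup_rt_tol)
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- order_features(as_features(out, source = "MR"))
  if (nrow(out)) out$feature_id <- sprintf("MR%04d", seq_len(nrow(out)))
  attr(out, "log") <- c(n_ms2 = length(ms2_scans(run)), n_candidates = nrow(cand),
                        n_novel = nrow(novel), n_valid = nrow(out))
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(mz = numeric(0), rt = numeric(0), reason = character(0))
  out
}
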