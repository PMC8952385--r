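#' Targeted-extraction configuration
#'
#' Defaults: targets confirmed in the raw data within 0.01 Th and 30 s,
#' 3-fold local-noise requirement and the 4-consecutive-scan rule shared
#' with the rescue tier.
#'
#' @param mass_tol,rt_tol confirmation window (Th, seconds).
#' @param noise_fold required apex-to-local-noise ratio.
#' @param min_consecutive_scans minimum consecutive MS1 scans with signal;
#'   also the scan distance within which a rescued (MR) apex vetoes a
#'   targeted candidate.
#' @param noise_floor fallback noise level (counts).
#' @return a `tl_config` list.
#' @export
tl_config <- function(mass_tol = 0.01, rt_tol = 30, noise_fold = 3,
                      min_consecutive_scans = 4, noise_floor = 100) {
  stopifnot(mass_tol > 0, rt_tol > 0, noise_fold > 0,
            min_consecutive_scans > 0, noise_floor > 0)
  structure(as.list(environment()), class = "tl_config")
}

#' Extract targeted compounds from raw data (the TL tier)
#'
#' Each target not already matched by an existing (PP or MR) feature within
#' `(mass_tol, rt_tol)` is searched directly in the raw data: its EIC is
#' extracted, the apex located, and the candidate validated against the
#' local noise (`noise_fold`) and the consecutive-scan rule. A candidate is
#' also rejected when an MR feature within `mass_tol` in m/z has its apex
#' within `min_consecutive_scans` MS1 scans of the target's apex (the
#' rescue tier already owns that signal). Each target yields at most one
#' feature; the per-target outcome is attached as attribute `report`
#' (reasons: `already_extracted`, `no_signal`, `noise_fail`,
#' `consecutive_fail`, `mr_collision`, `extracted`).
#'
#' @param run an `ms_run`.
#' @param targets data.frame `name`, `mz`, `rt` (seconds).
#' @param existing feature data.frame of PP and MR features.
#' @param cfg a [tl_config()].
#' @return feature data.frame (source `"TL"`), sorted by (mz, rt).
#' @export
run_tl <- function(run, targets, existing = empty_features(), cfg = tl_config()) {
  if (is.null(targets) || nrow(targets) == 0L)
    stop_pr("targeted list is empty", "config")
  targets <- targets[order(targets$mz, targets$rt, targets$name), , drop = FALSE]
  rts <- ms1_rts(run)
  mr <- existing[existing$source == "MR", , drop = FALSE]
  mr_ord <- if (nrow(mr)) vapply(mr$rt, function(r) which.min(abs(rts - r)), integer(1)) else integer(0)

  feats <- list()
  report <- list()
  note <- function(name, status, reason = NA_character_) {
    report[[length(report) + 1L]] <<- data.frame(
      name = name, status = status, reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    hit <- nrow(existing) > 0L &&
      any(abs(existing$mz - tg$mz) <= cfg$mass_tol &
          abs(existing$rt - tg$rt) <= cfg$rt_tol)
    if (hit) { note(tg$name, "rejected", "already_extracted"); next }
    eic <- extract_eic(run, tg$mz, cfg$mass_tol, tg$rt, cfg$rt_tol)
    if (nrow(eic) == 0L || all(eic$intensity <= 0)) {
      note(tg$name, "rejected", "no_signal"); next
    }
    at <- which.max(eic$intensity)
    apex_int <- eic$intensity[at]
    rr <- run_around(eic$intensity > 0, at)
    noise <- estimate_local_noise(eic, c(eic$rt[rr[1]], eic$rt[rr[2]]),
                                  floor = cfg$noise_floor)
    if (!(apex_int > cfg$noise_fold * noise)) {
      note(tg$name, "rejected", "noise_fail"); next
    }
    if (rr[2] - rr[1] + 1L < cfg$min_consecutive_scans) {
      note(tg$name, "rejected", "consecutive_fail"); next
    }
    if (nrow(mr)) {
      apex_ord <- which.min(abs(rts - eic$rt[at]))
      clash <- abs(mr$mz - tg$mz) <= cfg$mass_tol &
        abs(mr_ord - apex_ord) <= cfg$min_consecutive_scans
      if (any(clash)) { note(tg$name, "rejected", "mr_collision"); next }
    }
    seg <- rr[1]:rr[2]
    wts <- eic$intensity[seg]
    mzv <- eic$mz[seg]
    okm <- !is.na(mzv) & wts > 0
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = NA_character_,
      mz = if (any(okm)) sum(mzv[okm] * wts[okm]) / sum(wts[okm]) else tg$mz,
      rt = eic$rt[at], rtmin = eic$rt[rr[1]], rtmax = eic$rt[rr[2]],
      intensity = apex_int, area = trapz(eic$rt[seg], wts),
      source = "TL", ms2_scan = NA_integer_,
      sn = apex_int / noise, stringsAsFactors = FALSE
    )
    note(tg$name, "extracted")
  }
  out <- if (length(feats)) do.call(rbind, feats) else empty_features()
  out <- order_features(as_features(out, source = "TL"))
  if (nrow(out)) out$feature_id <- sprintf("TL%04d", seq_len(nrow(out)))
  attr(out, "report") <- do.call(rbind, report)
  out
}
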