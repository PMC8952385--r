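#' Alignment configuration
#'
#' Density-style grouping in overlapping m/z slices. Defaults: RT bandwidth
#' 5 s, slice width 0.015 Th, groups kept when present in at least half the
#' samples (and at least one sample), at most 100 groups per slice.
#'
#' @param bw Gaussian kernel bandwidth (seconds) for the RT density.
#' @param mzwid m/z slice width (Th); slices advance by `mzwid / 2`.
#' @param minfrac minimum fraction of samples a group must cover.
#' @param minsamp minimum number of samples a group must cover.
#' @param max_groups_per_slice cap on density peaks pursued per slice.
#' @return an `align_config` list.
#' @export
align_config <- function(bw = 5, mzwid = 0.015, minfrac = 0.5,
                         minsamp = 1, max_groups_per_slice = 100) {
  stopifnot(bw > 0, mzwid > 0, minfrac > 0, minfrac <= 1,
            minsamp >= 1, max_groups_per_slice >= 1)
  structure(as.list(environment()), class = "align_config")
}

#' Group features across samples
#'
#' Features from all samples are binned into overlapping m/z slices of
#' width `mzwid` (advancing by `mzwid / 2`); within a slice, peaks of the
#' Gaussian RT density (bandwidth `bw`) define groups. A group is kept iff
#' it has members from at least `max(minsamp, ceiling(minfrac * n_samples))`
#' samples; each sample contributes its single nearest-RT feature.
#' Duplicate groups arising from slice overlap are removed.
#'
#' @param tables named list (sample_id -> feature data.frame).
#' @param cfg an [align_config()].
#' @return a `feature_groups` object: list with `groups` (data.frame
#'   `group_id`, `mz_med`, `rt_med`, `source_summary`), `members` (per-group
#'   data.frame of member features with a `sample_id` column), `intensities`
#'   (group x sample matrix, `NA` where missing) and `filled` (logical
#'   matrix, all `FALSE` until [gap_fill()]).
#' @export
group_features <- function(tables, cfg = align_config()) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  samples <- sort(names(tables))
  n_samp <- length(samples)
  need <- max(cfg$minsamp, ceiling(cfg$minfrac * n_samp))

  all_ft <- do.call(rbind, lapply(samples, function(s) {
    ft <- tables[[s]]
    if (is.null(ft) || nrow(ft) == 0L) return(NULL)
    cbind(ft, sample_id = s, stringsAsFactors = FALSE)
  }))
  groups <- list()
  if (!is.null(all_ft) && nrow(all_ft) > 0L) {
    all_ft <- all_ft[order(all_ft$mz, all_ft$rt), , drop = FALSE]
    mz_lo <- floor(min(all_ft$mz) / (cfg$mzwid / 2)) * (cfg$mzwid / 2)
    starts <- seq(mz_lo - cfg$mzwid / 2, max(all_ft$mz), by = cfg$mzwid / 2)
    for (s0 in starts) {
      in_slice <- which(all_ft$mz >= s0 & all_ft$mz <= s0 + cfg$mzwid)
      if (length(in_slice) < need) next
      sl <- all_ft[in_slice, , drop = FALSE]
      rts <- sl$rt
      if (length(unique(rts)) == 1L) {
        cands <- list(seq_len(nrow(sl)))
      } else {
        d <- density(rts, bw = cfg$bw, from = min(rts) - 3 * cfg$bw,
                     to = max(rts) + 3 * cfg$bw, n = 512)
        pk <- local_maxima(d$y)
        if (length(pk) == 0L) pk <- which.max(d$y)
        pk <- pk[order(-d$y[pk])]
        pk <- head(pk, cfg$max_groups_per_slice)
        used <- logical(nrow(sl))
        cands <- list()
        for (p in pk) {
          # region between flanking density minima
          lo <- p; while (lo > 1L && d$y[lo - 1L] < d$y[lo]) lo <- lo - 1L
          hi <- p; while (hi < length(d$y) && d$y[hi + 1L] < d$y[hi]) hi <- hi + 1L
          sel <- which(!used & rts >= d$x[lo] & rts <= d$x[hi])
          if (length(sel)) { used[sel] <- TRUE; cands[[length(cands) + 1L]] <- sel }
        }
      }
      for (sel in cands) {
        mem <- sl[sel, , drop = FALSE]
        if (length(unique(mem$sample_id)) < need) next
        rt_med <- median(mem$rt)
        # one feature per sample: nearest RT to the group median
        keep <- unlist(lapply(split(seq_len(nrow(mem)), mem$sample_id), function(ii) {
          ii[which.min(abs(mem$rt[ii] - rt_med))]
        }))
        mem <- mem[sort(keep), , drop = FALSE]
        groups[[length(groups) + 1L]] <- mem
      }
    }
  }
  # deduplicate groups found in overlapping slices
  if (length(groups)) {
    mz_med <- vapply(groups, function(g) median(g$mz), numeric(1))
    rt_med <- vapply(groups, function(g) median(g$rt), numeric(1))
    sizes <- vapply(groups, nrow, integer(1))
    ord <- order(-sizes, mz_med, rt_med)
    keep <- logical(length(groups))
    for (i in ord) {
      kept <- which(keep)
      dup <- length(kept) > 0L &&
        any(abs(mz_med[kept] - mz_med[i]) <= cfg$mzwid / 2 &
            abs(rt_med[kept] - rt_med[i]) <= cfg$bw / 2)
      keep[i] <- !dup
    }
    groups <- groups[keep]
    mz_med <- mz_med[keep]; rt_med <- rt_med[keep]
    ord <- order(mz_med, rt_med)
    groups <- groups[ord]; mz_med <- mz_med[ord]; rt_med <- rt_med[ord]
  } else {
    mz_med <- rt_med <- numeric(0)
  }

  n_grp <- length(groups)
  intens <- matrix(NA_real_, n_grp, n_samp, dimnames = list(NULL, samples))
  src <- character(n_grp)
  for (g in seq_len(n_grp)) {
    mem <- groups[[g]]
    intens[g, mem$sample_id] <- mem$intensity
    tab <- table(mem$source)
    src[g] <- paste(paste0(names(tab), ":", as.integer(tab)), collapse = ";")
  }
  structure(list(
    groups = data.frame(
      group_id = sprintf("G%04d", seq_len(n_grp)),
      mz_med = mz_med, rt_med = rt_med, source_summary = src,
      stringsAsFactors = FALSE
    ),
    members = groups,
    intensities = intens,
    filled = matrix(FALSE, n_grp, n_samp, dimnames = list(NULL, samples)),
    samples = samples, cfg = cfg
  ), class = "feature_groups")
}

#' Fill missing group intensities from the raw data
#'
#' For every (group, sample) cell without a member feature, the intensity is
#' back-extracted as the maximum EIC intensity in the box
#' `[mz_med +/- mass_tol] x [rt_med +/- bw]` of that sample's raw run (0
#' when there is no signal). Filled cells are flagged in `$filled`.
#'
#' @param grp a `feature_groups` object.
#' @param runs named list (sample_id -> `ms_run`).
#' @param cfg an [align_config()]; defaults to the one used for grouping.
#' @param mass_tol m/z half-window (Th) for back-extraction.
#' @return the completed `feature_groups` object.
#' @export
gap_fill <- function(grp, runs, cfg = grp$cfg, mass_tol = 0.01) {
  miss_samp <- setdiff(grp$samples, names(runs))
  if (length(miss_samp))
    stop_pr(paste0("no run provided for sample(s): ", paste(miss_samp, collapse = ", ")), "config")
  for (g in seq_len(nrow(grp$groups))) {
    for (s in grp$samples) {
      if (!is.na(grp$intensities[g, s])) next
      eic <- extract_eic(runs[[s]], grp$groups$mz_med[g], mass_tol,
                         grp$groups$rt_med[g], cfg$bw)
      grp$intensities[g, s] <- if (nrow(eic)) max(eic$intensity) else 0
      grp$filled[g, s] <- TRUE
    }
  }
  grp
}

#' Flatten a `feature_groups` object to one table
#'
#' @param grp a `feature_groups` object.
#' @return data.frame: group metadata, one intensity column per sample and
#'   a `filled_flags` column listing gap-filled samples.
#' @export
aligned_table <- function(grp) {
  flags <- apply(grp$filled, 1L, function(f)
    paste(grp$samples[f], collapse = ";"))
  cbind(grp$groups, as.data.frame(grp$intensities),
        filled_flags = flags, stringsAsFactors = FALSE)
}

#' @export
print.feature_groups <- function(x, ...) {
  cat(sprintf("<feature_groups> %d groups x %d samples (%d cells filled)\n",
              nrow(x$groups), length(x$samples), sum(x$filled)))
  invisible(x)
}
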