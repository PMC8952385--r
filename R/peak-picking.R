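#' Peak-picking configuration
#'
#' Defaults follow common reversed-phase practice: 10 ppm m/z tolerance,
#' peak width 5-20 s (use 10-60 s for HILIC separations), S/N threshold 3,
#' minimum m/z separation 0.01 Th, prefilter of 3 points at >= 100 counts
#' and a 100-count noise floor.
#'
#' @param ppm relative m/z tolerance (ppm) for extending an ROI trace.
#' @param peakwidth_min,peakwidth_max accepted chromatographic peak width
#'   (FWHM, seconds).
#' @param snthresh minimum signal-to-noise ratio.
#' @param mzdiff minimum m/z difference (Th) between reported features with
#'   overlapping RT ranges.
#' @param prefilter_k,prefilter_intensity an ROI must contain at least
#'   `prefilter_k` points with intensity >= `prefilter_intensity`.
#' @param noise intensity floor (counts); also the fallback baseline/noise
#'   estimate when an ROI has too few flanking points.
#' @param max_scan_gap consecutive MS1 scans an ROI trace may miss before it
#'   is closed.
#' @return a `pp_config` list.
#' @export
pp_config <- function(ppm = 10, peakwidth_min = 5, peakwidth_max = 20,
                      snthresh = 3, mzdiff = 0.01, prefilter_k = 3,
                      prefilter_intensity = 100, noise = 100,
                      max_scan_gap = 2) {
  stopifnot(ppm > 0, peakwidth_min > 0, peakwidth_max > peakwidth_min,
            snthresh > 0, mzdiff > 0, prefilter_k > 0,
            prefilter_intensity > 0, noise > 0, max_scan_gap >= 0)
  structure(as.list(environment()), class = "pp_config")
}

#' Detect regions of interest (ROIs)
#'
#' Walks the MS1 scans in RT order, extending a trace when a centroid falls
#' within `ppm` of the trace's running intensity-weighted mean m/z. A trace
#' tolerates up to `max_scan_gap` consecutive scans without a match. Traces
#' failing the prefilter (fewer than `prefilter_k` points at
#' `prefilter_intensity` or more) or never exceeding the noise floor are
#' dropped.
#'
#' @param run an `ms_run`.
#' @param cfg a [pp_config()].
#' @return list of ROIs; each has `mz_center`, `scan_span` (first/last MS1
#'   scan_index) and `trace`, a data.frame with columns `ord` (MS1 ordinal),
#'   `scan_index`, `rt`, `mz`, `intensity`.
#' @export
detect_rois <- function(run, cfg = pp_config()) {
  ms1_pos <- run$ms1_index + 1L
  n_scan <- length(ms1_pos)
  if (n_scan < cfg$prefilter_k)
    stop_pr("run has fewer MS1 scans than prefilter_k", "empty_run")
  rts <- ms1_rts(run)

  # active traces, kept in parallel vectors
  t_mean <- numeric(0); t_w <- numeric(0); t_last <- integer(0)
  t_pts <- list()
  done <- list()

  finalize <- function(pts) {
    m <- do.call(rbind, pts)
    if (nrow(m) < cfg$prefilter_k) return(NULL)
    if (sum(m[, 5] >= cfg$prefilter_intensity) < cfg$prefilter_k) return(NULL)
    if (max(m[, 5]) <= cfg$noise) return(NULL)
    list(
      mz_center = sum(m[, 4] * m[, 5]) / sum(m[, 5]),
      scan_span = c(m[1, 2], m[nrow(m), 2]),
      trace = data.frame(ord = as.integer(m[, 1]), scan_index = as.integer(m[, 2]),
                         rt = m[, 3], mz = m[, 4], intensity = m[, 5])
    )
  }

  for (j in seq_len(n_scan)) {
    sp <- run$spectra[[ms1_pos[j]]]
    mz <- sp$mz; ints <- sp$intensity
    nc <- length(mz)
    matched_trace <- integer(0)
    if (nc > 0L && length(t_mean) > 0L) {
      o <- order(t_mean)
      tm <- t_mean[o]
      lo <- findInterval(mz, tm)
      hi <- pmin(lo + 1L, length(tm))
      lo <- pmax(lo, 1L)
      d_lo <- abs(mz - tm[lo]); d_hi <- abs(mz - tm[hi])
      pick <- ifelse(d_hi < d_lo, hi, lo)
      cand <- o[pick]
      ok <- ppm_diff(mz, t_mean[cand]) <= cfg$ppm
      # one centroid per trace: nearest wins
      assign_trace <- rep(NA_integer_, nc)
      if (any(ok)) {
        idx <- which(ok)
        dd <- abs(mz[idx] - t_mean[cand[idx]])
        idx <- idx[order(dd)]
        taken <- logical(length(t_mean))
        for (i in idx) {
          tr <- cand[i]
          if (!taken[tr]) { taken[tr] <- TRUE; assign_trace[i] <- tr }
        }
      }
      matched_trace <- assign_trace
    } else {
      matched_trace <- rep(NA_integer_, nc)
    }
    if (nc > 0L) {
      for (i in seq_len(nc)) {
        tr <- matched_trace[i]
        pt <- c(j, sp$scan_index, sp$rt, mz[i], ints[i])
        if (is.na(tr)) {
          t_mean <- c(t_mean, mz[i]); t_w <- c(t_w, ints[i])
          t_last <- c(t_last, j); t_pts[[length(t_pts) + 1L]] <- list(pt)
        } else {
          w <- t_w[tr] + ints[i]
          t_mean[tr] <- (t_mean[tr] * t_w[tr] + mz[i] * ints[i]) / max(w, .Machine$double.eps)
          t_w[tr] <- w
          t_last[tr] <- j
          t_pts[[tr]][[length(t_pts[[tr]]) + 1L]] <- pt
        }
      }
    }
    # close stale traces
    stale <- which(j - t_last > cfg$max_scan_gap)
    if (length(stale)) {
      for (k in stale) {
        roi <- finalize(t_pts[[k]])
        if (!is.null(roi)) done[[length(done) + 1L]] <- roi
      }
      keep <- setdiff(seq_along(t_mean), stale)
      t_mean <- t_mean[keep]; t_w <- t_w[keep]; t_last <- t_last[keep]
      t_pts <- t_pts[keep]
    }
  }
  for (k in seq_along(t_mean)) {
    roi <- finalize(t_pts[[k]])
    if (!is.null(roi)) done[[length(done) + 1L]] <- roi
  }
  if (length(done)) done[order(vapply(done, `[[`, numeric(1), "mz_center"))] else done
}

# Mexican-hat (Ricker) wavelet sampled at integer offsets for scale a.
ricker <- function(a) {
  hw <- max(2L, ceiling(5 * a))
  x <- (-hw):hw / a
  (1 - x^2) * exp(-x^2 / 2) / sqrt(a)
}

# CWT coefficients for one scale; same length as y (zero-padded edges).
cwt_row <- function(y, kern) {
  hw <- (length(kern) - 1L) %/% 2L
  ypad <- c(rep(0, hw), y, rep(0, hw))
  f <- stats::filter(ypad, kern, sides = 2)
  as.numeric(f[(hw + 1L):(hw + length(y))])
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

# Interpolated full width at half maximum around apex `a` (grid indices).
fwhm_width <- function(rts, y, a, baseline) {
  half <- baseline + (y[a] - baseline) / 2
  n <- length(y)
  cross <- function(x1, x2, y1, y2) {
    if (y2 == y1) (x1 + x2) / 2 else x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  }
  left <- rts[1]
  i <- a
  while (i > 1L && y[i - 1L] > half) i <- i - 1L
  if (i > 1L) left <- cross(rts[i - 1L], rts[i], y[i - 1L], y[i])
  right <- rts[n]
  i <- a
  while (i < n && y[i + 1L] > half) i <- i + 1L
  if (i < n) right <- cross(rts[i], rts[i + 1L], y[i], y[i + 1L])
  right - left
}

# Boundary descent from the apex: stop where the trace falls to the
# baseline + noise band, hits a zero gap, or turns up again at a local
# minimum below 10% of the apex-above-baseline.
descend <- function(y, a, thr, baseline) {
  n <- length(y)
  rel <- y[a] - baseline
  lo <- a
  while (lo > 1L) {
    v <- y[lo - 1L]
    if (v <= thr || v <= 0) break
    if (v > y[lo] && (y[lo] - baseline) < 0.1 * rel) break
    lo <- lo - 1L
  }
  hi <- a
  while (hi < n) {
    v <- y[hi + 1L]
    if (v <= thr || v <= 0) break
    if (v > y[hi] && (y[hi] - baseline) < 0.1 * rel) break
    hi <- hi + 1L
  }
  c(lo, hi)
}

#' Pick chromatographic peaks (the PP tier)
#'
#' Within each ROI, candidate apexes are located by Mexican-hat
#' continuous-wavelet-transform maxima across ~10 logarithmically spaced
#' scales spanning the peak-width bounds. A candidate is kept iff its FWHM
#' lies in `[peakwidth_min, peakwidth_max]` and its S/N
#' `(apex - baseline) / max(noise_sd, 1)` reaches `snthresh`, where baseline
#' and noise_sd are the median and MAD of ROI trace intensities outside the
#' peak (fallback: the configured noise floor when fewer than 4 such points
#' exist). Features closer than `mzdiff` in m/z with overlapping RT ranges
#' are merged keeping the higher apex. Each feature is assigned the MS2 scan
#' (if any) whose precursor matches within `ms2_mass_tol` and whose trigger
#' RT lies within the peak's RT range.
#'
#' @inheritParams detect_rois
#' @param ms2_mass_tol m/z tolerance (Th) for attaching MS2 scans.
#' @return a feature `data.frame` (source `"PP"`), ordered by (mz, rt).
#' @export
pick_peaks <- function(run, cfg = pp_config(), ms2_mass_tol = 0.01) {
  rois <- detect_rois(run, cfg)
  cycle <- ms1_cycle_time(run)
  rts_all <- ms1_rts(run)
  scales <- unique(pmax(1, round(exp(seq(
    log(max(1, cfg$peakwidth_min / cycle / 2)),
    log(max(2, cfg$peakwidth_max / cycle / 2)),
    length.out = 10
  )))))
  kerns <- lapply(scales, ricker)

  rows <- list()
  for (roi in rois) {
    tr <- roi$trace
    ords <- tr$ord[1]:tr$ord[nrow(tr)]
    y <- numeric(length(ords))
    pos <- match(tr$ord, ords)
    y[pos] <- tr$intensity
    mzg <- rep(NA_real_, length(ords)); mzg[pos] <- tr$mz
    rts <- rts_all[ords]
    if (length(y) < 3L) next

    coef_max <- rep(-Inf, length(y))
    best_scale <- rep(scales[1], length(y))
    for (si in seq_along(scales)) {
      cw <- cwt_row(y, kerns[[si]])
      upd <- cw > coef_max
      coef_max[upd] <- cw[upd]
      best_scale[upd] <- scales[si]
    }
    cand <- local_maxima(coef_max)
    cand <- cand[coef_max[cand] > 0]
    if (length(y) >= 2L && y[1] > 0 && coef_max[1] > 0 && (length(cand) == 0L || min(cand) > 3L))
      cand <- c(1L, cand) # edge peak guard
    if (length(cand) == 0L) next

    apexes <- integer(0)
    for (ci in cand) {
      w <- max(1L, round(best_scale[ci]))
      win <- max(1L, ci - w):min(length(y), ci + w)
      apexes <- c(apexes, win[which.max(y[win])])
    }
    apexes <- unique(apexes[y[apexes] > 0])

    for (a in apexes) {
      a_scale <- best_scale[a]
      prov <- max(1L, a - 2L * a_scale):min(length(y), a + 2L * a_scale)
      flank0 <- tr$intensity[!(tr$ord %in% ords[prov])]
      if (length(flank0) >= 4L) {
        b0 <- median(flank0); s0 <- mad(flank0)
      } else {
        # no flanking observations: no evidence of a local baseline, so the
        # peak extends to the edge of detection and the configured noise
        # floor stands in for the S/N estimate below
        b0 <- 0; s0 <- 0
      }
      bd <- descend(y, a, thr = b0 + s0, baseline = b0)
      lo <- bd[1]; hi <- bd[2]
      if (hi <= lo) next
      flank <- tr$intensity[tr$ord < ords[lo] | tr$ord > ords[hi]]
      if (length(flank) >= 4L) {
        baseline <- median(flank); noise_sd <- mad(flank)
      } else {
        baseline <- cfg$noise; noise_sd <- cfg$noise
      }
      apex_int <- y[a]
      if (apex_int <= cfg$noise || apex_int <= baseline) next
      sn <- (apex_int - baseline) / max(noise_sd, 1)
      if (sn < cfg$snthresh) next
      width <- fwhm_width(rts, y, a, baseline)
      if (!is.finite(width) || width < cfg$peakwidth_min || width > cfg$peakwidth_max) next
      seg <- lo:hi
      wts <- y[seg]
      mzv <- mzg[seg]
      okm <- !is.na(mzv) & wts > 0
      if (!any(okm)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mz = sum(mzv[okm] * wts[okm]) / sum(wts[okm]),
        rt = rts[a], rtmin = rts[lo], rtmax = rts[hi],
        intensity = apex_int, area = trapz(rts[seg], y[seg]),
        sn = sn, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_features())
  ft <- do.call(rbind, rows)
  ft <- merge_close_features(ft, cfg$mzdiff)
  ft <- ft[order(ft$mz, ft$rt), , drop = FALSE]
  ft$feature_id <- sprintf("PP%04d", seq_len(nrow(ft)))
  ft$source <- "PP"
  ft$ms2_scan <- attach_ms2(run, ft, ms2_mass_tol)
  order_features(as_features(ft, source = "PP"))
}

# Merge features closer than mzdiff in m/z with overlapping RT ranges,
# keeping the higher apex.
merge_close_features <- function(ft, mzdiff) {
  if (nrow(ft) < 2L) return(ft)
  ft <- ft[order(-ft$intensity), , drop = FALSE]
  keep <- logical(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    kept <- which(keep)
    clash <- FALSE
    if (length(kept)) {
      dm <- abs(ft$mz[kept] - ft$mz[i]) < mzdiff
      ov <- ft$rtmin[kept] <= ft$rtmax[i] & ft$rtmax[kept] >= ft$rtmin[i]
      clash <- any(dm & ov)
    }
    keep[i] <- !clash
  }
  ft[keep, , drop = FALSE]
}

# For each feature, the MS2 scan with matching precursor m/z triggered
# inside the feature's RT range (highest precursor intensity wins).
attach_ms2 <- function(run, ft, mass_tol) {
  out <- rep(NA_integer_, nrow(ft))
  idx <- ms2_scans(run)
  if (length(idx) == 0L || nrow(ft) == 0L) return(out)
  pm <- vapply(run$spectra[idx + 1L], function(s) s$precursor_mz, numeric(1))
  pr <- vapply(run$spectra[idx + 1L], function(s) s$rt, numeric(1))
  pi <- vapply(run$spectra[idx + 1L], function(s) {
    v <- s$precursor_intensity; if (is.null(v) || is.na(v)) 0 else v
  }, numeric(1))
  for (i in seq_len(nrow(ft))) {
    sel <- which(abs(pm - ft$mz[i]) <= mass_tol & pr >= ft$rtmin[i] & pr <= ft$rtmax[i])
    if (length(sel)) out[i] <- idx[sel[which.max(pi[sel])]]
  }
  out
}
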