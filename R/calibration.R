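#' Build a calibration series
#'
#' One compound's serial-dilution record: concentrations, measured apex
#' intensities (`NA` where the compound was not detected), the tier that
#' detected each point, and the local noise intensity at the compound's
#' (m/z, RT) in the lowest-concentration run where it was detected.
#'
#' @param compound compound name.
#' @param concentration,intensity numeric vectors (same length);
#'   `intensity` is `NA` for undetected levels.
#' @param detected_by character vector of tier tags (`"PP"`, `"MR"`,
#'   `"TL"`) or `NA`.
#' @param noise_intensity local noise (counts).
#' @return a `calibration_series` list.
#' @export
calibration_series <- function(compound, concentration, intensity,
                               detected_by = NULL, noise_intensity = NA_real_) {
  stopifnot(length(concentration) == length(intensity), all(concentration >= 0))
  if (is.null(detected_by)) detected_by <- ifelse(is.na(intensity), NA_character_, "PP")
  structure(list(
    compound = compound,
    points = data.frame(concentration = concentration, intensity = intensity,
                        detected_by = detected_by, stringsAsFactors = FALSE),
    noise_intensity = noise_intensity
  ), class = "calibration_series")
}

#' Fit a calibration line
#'
#' Ordinary least squares of intensity on concentration over the detected
#' points.
#'
#' @param series a [calibration_series()].
#' @return list `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
fit_calibration <- function(series) {
  pts <- series$points[!is.na(series$points$intensity), , drop = FALSE]
  if (nrow(pts) < 2L)
    stop_pr("calibration requires at least 2 detected points", "insufficient_points")
  if (length(unique(pts$concentration)) < 2L)
    stop_pr("all detected points at one concentration; fit is degenerate", "degenerate_fit")
  fit <- lm(intensity ~ concentration, data = pts)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((pts$intensity - mean(pts$intensity))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_points = nrow(pts))
}

#' Estimate the limit of detection
#'
#' The MS intensity at 3x the local noise is fitted into the calibration
#' line: `LOD = (3 * noise - intercept) / slope`, floored at 0.
#'
#' @param series a [calibration_series()] (supplies `noise_intensity`).
#' @param fit result of [fit_calibration()].
#' @param noise_fold multiplier on the noise intensity (default 3).
#' @return concentration LOD (same units as the series concentrations).
#' @export
estimate_lod <- function(series, fit, noise_fold = 3) {
  if (!(fit$slope > 0))
    stop_pr("calibration slope must be positive for LOD estimation", "invalid_fit")
  max(0, (noise_fold * series$noise_intensity - fit$intercept) / fit$slope)
}

#' Compare LODs between the PP-only and joint tier-sets
#'
#' @param series_pp,series_joint named lists of [calibration_series()]
#'   (same compound names), built from the PP-only and the PP+MR+TL
#'   extractions of the same runs.
#' @return data.frame `compound,lod_pp,lod_joint,fold_change,slope,`
#'   `intercept,r2,n_points` (slope/intercept/r2/n from the joint fit).
#'   A tier-set that never detected the compound (fewer than 2 points)
#'   yields the not-reached sentinel `NA`.
#' @export
compare_lods <- function(series_pp, series_joint) {
  compounds <- union(names(series_pp), names(series_joint))
  one_lod <- function(series) {
    if (is.null(series)) return(list(lod = NA_real_, fit = NULL))
    fit <- tryCatch(fit_calibration(series), error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$slope > 0) || is.na(series$noise_intensity))
      return(list(lod = NA_real_, fit = fit))
    list(lod = estimate_lod(series, fit), fit = fit)
  }
  rows <- lapply(compounds, function(cp) {
    pp <- one_lod(series_pp[[cp]])
    jt <- one_lod(series_joint[[cp]])
    fit <- jt$fit
    data.frame(
      compound = cp, lod_pp = pp$lod, lod_joint = jt$lod,
      fold_change = if (!is.na(pp$lod) && !is.na(jt$lod) && jt$lod > 0)
        pp$lod / jt$lod else NA_real_,
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      r2 = if (is.null(fit)) NA_real_ else fit$r_squared,
      n_points = if (is.null(fit)) 0L else fit$n_points,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-tier relative standard deviation of replicate intensities
#'
#' Quality summary over replicate injections: per-feature RSD% =
#' sd/mean x 100 over replicates, averaged per extraction tier.
#'
#' @param intensities feature x replicate numeric matrix.
#' @param tiers character vector (one tag per feature row).
#' @return data.frame `tier`, `mean_rsd`, `n_features`.
#' @export
rsd_by_tier <- function(intensities, tiers) {
  stopifnot(nrow(intensities) == length(tiers))
  rsd <- apply(intensities, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v) * 100
  })
  agg <- aggregate(rsd, by = list(tier = tiers), FUN = mean, na.rm = TRUE)
  names(agg)[2] <- "mean_rsd"
  agg$n_features <- as.integer(table(tiers)[agg$tier])
  agg
}

#' Build PP-only and joint calibration series from dilution runs
#'
#' Matches each compound of `targets` against the per-dilution feature
#' tables of a tier-set within `(mass_tol, rt_tol)`; the detected intensity
#' is the matched feature's apex. The noise intensity is measured with
#' [estimate_local_noise()] at the compound's (m/z, RT) in the
#' lowest-concentration run where the tier-set detected it.
#'
#' @param runs named list (level name -> `ms_run`), one per dilution level.
#' @param features_by_level named list (level name -> feature data.frame)
#'   for one tier-set.
#' @param targets data.frame `name`, `mz`, `rt`.
#' @param dilutions named numeric vector (level name -> concentration).
#' @param mass_tol,rt_tol matching window (Th, seconds).
#' @param noise_rt_tol RT half-window (s) of the EIC used for noise
#'   estimation.
#' @param noise_floor fallback noise (counts).
#' @return named list of [calibration_series()].
#' @export
build_calibration_series <- function(runs, features_by_level, targets, dilutions,
                                     mass_tol = 0.01, rt_tol = 30,
                                     noise_rt_tol = 60, noise_floor = 100) {
  levels <- names(dilutions)
  stopifnot(all(levels %in% names(runs)), all(levels %in% names(features_by_level)))
  out <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    intens <- rep(NA_real_, length(levels))
    tier <- rep(NA_character_, length(levels))
    for (k in seq_along(levels)) {
      ft <- features_by_level[[levels[k]]]
      if (is.null(ft) || nrow(ft) == 0L) next
      sel <- which(abs(ft$mz - tg$mz) <= mass_tol & abs(ft$rt - tg$rt) <= rt_tol)
      if (length(sel)) {
        best <- sel[which.max(ft$intensity[sel])]
        intens[k] <- ft$intensity[best]
        tier[k] <- ft$source[best]
      }
    }
    det <- which(!is.na(intens))
    noise <- NA_real_
    if (length(det)) {
      lowest <- det[which.min(dilutions[det])]
      eic <- extract_eic(runs[[levels[lowest]]], tg$mz, mass_tol, tg$rt, noise_rt_tol)
      if (nrow(eic)) {
        # exclude the confirmation window around the expected peak; what is
        # left is the local chemical background
        noise <- estimate_local_noise(eic, c(tg$rt - rt_tol, tg$rt + rt_tol),
                                      floor = noise_floor)
      }
    }
    out[[tg$name]] <- calibration_series(tg$name, unname(dilutions), intens,
                                         tier, noise)
  }
  out
}
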