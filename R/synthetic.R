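#' Synthetic DDA run configuration
#'
#' The generator emulates a centroided DDA LC-MS run: MS1 scans on a fixed
#' cycle carrying a log-normal chemical baseline plus injected
#' chromatographic peaks, and top-N MS2 triggering with a dynamic-exclusion
#' window. Shape classes: `gaussian` (well-formed, FWHM within the picking
#' bounds), `fronting`/`tailing` (narrow cores with one-sided exponential
#' distortion), `shoulder` (two offset Gaussians) and `spike` (2-3-scan
#' pulse). The distorted classes are deliberately narrower than the minimum
#' peak width so they emulate the real-data population that conventional
#' picking misses but MS2 rescue recovers. Serial dilution scales injected
#' peak heights and, because diluting the sample dilutes its chemical
#' matrix, also the baseline and per-compound background ions
#' (`scale_baseline = TRUE`); the DDA trigger threshold and detector floor
#' are instrument constants and do not scale.
#'
#' @param seed integer; one seed yields one byte stream.
#' @param rt_span run length (seconds).
#' @param ms1_cycle MS1 period (seconds).
#' @param dda_top_n MS2 scans triggered per MS1 cycle.
#' @param dda_trigger_threshold minimum centroid intensity (counts) to
#'   trigger fragmentation.
#' @param dda_exclusion_cycles dynamic-exclusion window (MS1 cycles).
#' @param baseline_n baseline centroids per MS1 scan.
#' @param baseline_mean,baseline_sdlog log-normal baseline level (counts)
#'   and spread.
#' @param n_gaussian,n_distorted,n_subthreshold injected peak counts per
#'   class group.
#' @param mz_range m/z range (Th) peaks are drawn from.
#' @param height_range,distorted_height_range,subthreshold_height_range
#'   apex height ranges (counts), sampled log-uniformly.
#' @param sigma_range Gaussian peak sigma range (seconds).
#' @param narrow_sigma_range core sigma range (seconds) of distorted
#'   classes.
#' @param tau_range exponential distortion time constant range (seconds).
#' @param mz_jitter_ppm per-centroid Gaussian m/z jitter (ppm).
#' @param detector_threshold centroids below this intensity are not
#'   recorded (counts).
#' @param compound_background inject a dilution-scaled background ion near
#'   each compound's m/z (inside the 0.01 Th confirmation window but
#'   outside the 10 ppm ROI tolerance) so local-noise estimation has
#'   material to work with; only geometrically possible for m/z below
#'   ~450 Th.
#' @param scale_baseline scale baseline/background with dilution.
#' @param dilution_factors documented default dilution ladder.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 42, rt_span = 600, ms1_cycle = 1,
                         dda_top_n = 3, dda_trigger_threshold = 200,
                         dda_exclusion_cycles = 2,
                         baseline_n = 60, baseline_mean = 100,
                         baseline_sdlog = 0.3,
                         n_gaussian = 20, n_distorted = 10, n_subthreshold = 5,
                         n_spike = 0,
                         mz_range = c(100, 900),
                         height_range = c(5e2, 2e5),
                         distorted_height_range = c(4e3, 4e4),
                         subthreshold_height_range = c(150, 280),
                         sigma_range = c(2.5, 5),
                         narrow_sigma_range = c(0.45, 0.65),
                         tau_range = c(0.2, 0.4),
                         mz_jitter_ppm = 2, detector_threshold = 1,
                         compound_background = TRUE, scale_baseline = TRUE,
                         dilution_factors = c(1, 0.5, 0.25, 0.1)) {
  if (rt_span < 10 * ms1_cycle)
    stop_pr("rt_span must cover at least 10 MS1 cycles", "config")
  stopifnot(n_gaussian >= 0, n_distorted >= 0, n_subthreshold >= 0,
            diff(mz_range) > 0, dda_top_n >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# Peak-normalized shape value at offsets dt from the nominal center.
shape_value <- function(class, dt, sigma, tau, cycle) {
  g <- function(x, s) exp(-x^2 / (2 * s^2))
  switch(class,
    gaussian = g(dt, sigma),
    tailing = ifelse(dt <= 0, g(dt, sigma),
                     0.5 * g(dt, sigma) + 0.5 * exp(-dt / tau)),
    fronting = ifelse(dt >= 0, g(dt, sigma),
                      0.5 * g(dt, sigma) + 0.5 * exp(dt / tau)),
    shoulder = (g(dt, sigma) + 0.6 * g(dt - 1.8 * sigma, sigma)) / shoulder_max(sigma),
    spike = pmax(0, 1 - abs(dt) / (1.2 * cycle)),
    stop_pr(paste0("unknown shape class: ", class), "config")
  )
}

shoulder_max <- function(sigma) {
  x <- seq(-3 * sigma, 5 * sigma, length.out = 400)
  max(exp(-x^2 / (2 * sigma^2)) + 0.6 * exp(-(x - 1.8 * sigma)^2 / (2 * sigma^2)))
}

# True apex RT offset of a shape relative to its nominal center.
shape_apex_offset <- function(class, sigma) {
  if (class != "shoulder") return(0)
  x <- seq(-3 * sigma, 5 * sigma, length.out = 400)
  y <- exp(-x^2 / (2 * sigma^2)) + 0.6 * exp(-(x - 1.8 * sigma)^2 / (2 * sigma^2))
  x[which.max(y)]
}

# Draw the compound set; depends only on cfg$seed so replicate runs and
# dilution levels share the same compounds.
make_peak_set <- function(cfg, library = NULL) {
  n <- cfg$n_gaussian + cfg$n_distorted + cfg$n_spike + cfg$n_subthreshold
  if (n == 0L) {
    return(data.frame(compound_id = character(0), mz = numeric(0), rt = numeric(0),
                      height = numeric(0), class = character(0), sigma = numeric(0),
                      tau = numeric(0), bg_delta = numeric(0),
                      library = character(0), stringsAsFactors = FALSE))
  }
  with_seed(cfg$seed, {
    grid <- seq(cfg$mz_range[1], cfg$mz_range[2] - 0.1, by = 0.07)
    mz <- sort(sample(grid, n)) + runif(n, 0, 0.02)
    rt <- runif(n, 0.08 * cfg$rt_span, 0.92 * cfg$rt_span)
    logu <- function(k, rng) exp(runif(k, log(rng[1]), log(rng[2])))
    classes <- c(
      rep("gaussian", cfg$n_gaussian),
      if (cfg$n_distorted > 0)
        rep_len(c("tailing", "fronting", "shoulder"), cfg$n_distorted),
      rep("spike", cfg$n_spike),
      rep("gaussian", cfg$n_subthreshold)
    )
    height <- c(
      logu(cfg$n_gaussian, cfg$height_range),
      logu(cfg$n_distorted, cfg$distorted_height_range),
      logu(cfg$n_spike, cfg$distorted_height_range),
      logu(cfg$n_subthreshold, cfg$subthreshold_height_range)
    )
    sigma <- ifelse(classes == "gaussian",
                    runif(n, cfg$sigma_range[1], cfg$sigma_range[2]),
                    runif(n, cfg$narrow_sigma_range[1], cfg$narrow_sigma_range[2]))
    tau <- runif(n, cfg$tau_range[1], cfg$tau_range[2])
    # background ion inside the 0.01 Th window but > 20 ppm from the peak
    bg_delta <- rep(NA_real_, n)
    if (isTRUE(cfg$compound_background)) {
      lo <- mz * 20e-6
      ok <- lo < 0.009
      bg_delta[ok] <- runif(sum(ok), pmin(lo[ok] + 1e-4, 0.009), 0.009) *
        sample(c(-1, 1), sum(ok), replace = TRUE)
    }
    lib_names <- rep(NA_character_, n)
    if (!is.null(library) && length(library) > 0L) {
      k <- min(length(library), n)
      lib_names[seq_len(k)] <- vapply(library[seq_len(k)], `[[`, character(1),
                                      "compound_name")
      mz[seq_len(k)] <- vapply(library[seq_len(k)], `[[`, numeric(1), "precursor_mz")
    }
    data.frame(
      compound_id = sprintf("C%03d", seq_len(n)), mz = mz, rt = rt,
      height = height, class = classes, sigma = sigma, tau = tau,
      bg_delta = bg_delta, library = lib_names, stringsAsFactors = FALSE
    )
  })
}

#' Generate one synthetic DDA run with ground truth
#'
#' @param cfg a [synth_config()].
#' @param dilution dilution factor applied to injected peak heights (and,
#'   by default, to the chemical baseline; see [synth_config()]).
#' @param sample_id sample identifier for the run.
#' @param path optional path; when given, the run is also written as mzML.
#' @param run_seed seed for run-level noise (baseline, jitter, DDA order);
#'   defaults to `cfg$seed`. The compound set always derives from
#'   `cfg$seed`, so replicates share compounds.
#' @param library optional list of [read_msp()] entries; the first
#'   compounds are assigned these precursor m/z and fragment patterns.
#' @return list with `run` (an `ms_run`), `truth` (ground-truth
#'   data.frame: one row per injected peak with true m/z, apex RT, height,
#'   shape class, MS2-trigger count) and `path`.
#' @export
generate_run <- function(cfg, dilution = 1, sample_id = "S1", path = NULL,
                         run_seed = NULL, library = NULL) {
  stopifnot(inherits(cfg, "synth_config"), dilution > 0)
  if (is.null(run_seed)) run_seed <- cfg$seed
  peaks <- make_peak_set(cfg, library = library)
  lib_by_name <- if (!is.null(library))
    setNames(library, vapply(library, `[[`, character(1), "compound_name")) else list()
  bscale <- if (isTRUE(cfg$scale_baseline)) dilution else 1

  scan_times <- seq(0, cfg$rt_span, by = cfg$ms1_cycle)
  support <- pmax(6 * peaks$sigma + 8 * peaks$tau, 4 * cfg$ms1_cycle)
  n_ms2_trig <- integer(nrow(peaks))

  spectra <- list()
  with_seed(run_seed, {
    excl_mz <- numeric(0); excl_until <- numeric(0)
    scan_no <- 0L
    for (t in scan_times) {
      # chemical baseline
      b_mz <- runif(cfg$baseline_n, cfg$mz_range[1], cfg$mz_range[2])
      b_int <- rlnorm(cfg$baseline_n, log(cfg$baseline_mean * bscale), cfg$baseline_sdlog)
      src <- rep(0L, cfg$baseline_n)
      # per-compound background ions
      bg <- which(!is.na(peaks$bg_delta))
      if (length(bg)) {
        g_mz <- peaks$mz[bg] + peaks$bg_delta[bg]
        g_int <- rlnorm(length(bg), log(cfg$baseline_mean * bscale * 0.9), 0.3)
        b_mz <- c(b_mz, g_mz); b_int <- c(b_int, g_int); src <- c(src, rep(0L, length(bg)))
      }
      # injected peaks
      act <- which(abs(t - peaks$rt) <= support)
      if (length(act)) {
        sv <- vapply(act, function(k) shape_value(
          peaks$class[k], t - peaks$rt[k], peaks$sigma[k], peaks$tau[k],
          cfg$ms1_cycle), numeric(1))
        p_int <- peaks$height[act] * dilution * sv
        p_mz <- peaks$mz[act] * (1 + rnorm(length(act)) * cfg$mz_jitter_ppm * 1e-6)
        b_mz <- c(b_mz, p_mz); b_int <- c(b_int, p_int); src <- c(src, act)
      }
      keep <- b_int >= cfg$detector_threshold
      b_mz <- b_mz[keep]; b_int <- b_int[keep]; src <- src[keep]
      o <- order(b_mz)
      b_mz <- b_mz[o]; b_int <- b_int[o]; src <- src[o]
      # enforce strictly increasing m/z
      if (length(b_mz) > 1L) {
        d <- which(diff(b_mz) <= 0)
        while (length(d)) {
          b_mz[d + 1L] <- b_mz[d] + 1e-6
          d <- which(diff(b_mz) <= 0)
        }
      }
      ms1_scan_no <- scan_no
      spectra[[length(spectra) + 1L]] <- list(
        scan_index = scan_no, ms_level = 1L, rt = t,
        mz = b_mz, intensity = b_int,
        precursor_mz = NA_real_, precursor_intensity = NA_real_,
        precursor_scan_index = NA_integer_
      )
      scan_no <- scan_no + 1L
      # top-N DDA triggering with dynamic exclusion
      if (cfg$dda_top_n > 0L && length(b_int)) {
        live <- excl_until > t
        excl_mz <- excl_mz[live]; excl_until <- excl_until[live]
        eligible <- which(b_int >= cfg$dda_trigger_threshold)
        if (length(excl_mz) && length(eligible)) {
          blocked <- vapply(eligible, function(i)
            any(abs(excl_mz - b_mz[i]) <= 0.01), logical(1))
          eligible <- eligible[!blocked]
        }
        eligible <- eligible[order(-b_int[eligible])]
        picks <- head(eligible, cfg$dda_top_n)
        for (k in seq_along(picks)) {
          i <- picks[k]
          frag <- make_fragments(b_mz[i], b_int[i], src[i], peaks, lib_by_name)
          spectra[[length(spectra) + 1L]] <- list(
            scan_index = scan_no, ms_level = 2L,
            rt = t + cfg$ms1_cycle * k / (cfg$dda_top_n + 1),
            mz = frag$mz, intensity = frag$intensity,
            precursor_mz = b_mz[i], precursor_intensity = b_int[i],
            precursor_scan_index = ms1_scan_no
          )
          scan_no <- scan_no + 1L
          excl_mz <- c(excl_mz, b_mz[i])
          excl_until <- c(excl_until, t + cfg$dda_exclusion_cycles * cfg$ms1_cycle)
          if (src[i] > 0L) n_ms2_trig[src[i]] <- n_ms2_trig[src[i]] + 1L
        }
      }
    }
  })
  run <- new_run(spectra, sample_id = sample_id)
  truth <- data.frame(
    compound_id = peaks$compound_id, mz = peaks$mz,
    rt = peaks$rt + vapply(seq_len(nrow(peaks)), function(k)
      shape_apex_offset(peaks$class[k], peaks$sigma[k]), numeric(1)),
    height = peaks$height * dilution, shape = peaks$class,
    sigma = peaks$sigma, tau = peaks$tau,
    ms2_triggered = n_ms2_trig > 0L, n_ms2 = n_ms2_trig,
    library = peaks$library, dilution = dilution, sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_mzml(run, path)
  list(run = run, truth = truth, path = path)
}

# MS2 fragment pattern for a triggered precursor. Library compounds use
# their library fragments (5% multiplicative noise); other compounds get a
# reproducible pseudo-pattern derived from their index; baseline triggers
# get random fragments.
make_fragments <- function(prec_mz, prec_int, src, peaks, lib_by_name) {
  if (src > 0L && !is.na(peaks$library[src]) &&
      peaks$library[src] %in% names(lib_by_name)) {
    fr <- lib_by_name[[peaks$library[src]]]$fragments
    rel <- fr[, "intensity"] / max(fr[, "intensity"])
    int <- pmax(rel * prec_int * (1 + rnorm(nrow(fr)) * 0.05), 1)
    mz <- fr[, "mz"]
  } else if (src > 0L) {
    fracs <- c(0.18, 0.32, 0.45, 0.61, 0.83)
    off <- (src * 0.0371) %% 0.1
    mz <- prec_mz * fracs + off
    int <- c(100, 80, 60, 40, 20) * max(prec_int / 1000, 1) *
      (1 + rnorm(5) * 0.05)
  } else {
    mz <- sort(runif(5, 50, max(60, prec_mz - 1)))
    int <- runif(5, 10, 100)
  }
  o <- order(mz)
  list(mz = mz[o], intensity = pmax(int[o], 0.1))
}

#' Score extracted features against ground truth
#'
#' Matches found features to truth rows within `(mass_tol, rt_tol)`,
#' greedily by scaled distance, at most one feature per truth row and vice
#' versa. Reports recall per shape class, overall recall and precision, and
#' per-tier feature counts.
#'
#' @param found feature data.frame.
#' @param truth ground-truth data.frame from [generate_run()].
#' @param mass_tol,rt_tol matching window (Th, seconds).
#' @return list `recall`, `recall_by_class`, `precision`,
#'   `precision_defined`, `n_found_by_tier`, `matches` (data.frame
#'   `feature_id`, `compound_id`), `truth_matched` (logical vector).
#' @export
score_extraction <- function(found, truth, mass_tol = 0.01, rt_tol = 30) {
  nf <- nrow(found); nt <- nrow(truth)
  matched_f <- rep(NA_integer_, nf)
  matched_t <- rep(NA_integer_, nt)
  if (nf > 0L && nt > 0L) {
    pairs <- list()
    for (i in seq_len(nf)) {
      sel <- which(abs(truth$mz - found$mz[i]) <= mass_tol &
                   abs(truth$rt - found$rt[i]) <= rt_tol)
      for (j in sel) {
        pairs[[length(pairs) + 1L]] <- c(i, j,
          abs(truth$mz[j] - found$mz[i]) / mass_tol +
          abs(truth$rt[j] - found$rt[i]) / rt_tol)
      }
    }
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(pm[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; j <- pm[r, 2]
        if (is.na(matched_f[i]) && is.na(matched_t[j])) {
          matched_f[i] <- j; matched_t[j] <- i
        }
      }
    }
  }
  by_class <- if (nt > 0L) {
    tapply(!is.na(matched_t), truth$shape, mean)
  } else numeric(0)
  precision_defined <- nf > 0L
  list(
    recall = if (nt > 0L) mean(!is.na(matched_t)) else NA_real_,
    recall_by_class = by_class,
    precision = if (precision_defined) mean(!is.na(matched_f)) else 0,
    precision_defined = precision_defined,
    n_found_by_tier = if (nf > 0L) table(found$source) else table(character(0)),
    matches = data.frame(
      feature_id = found$feature_id[!is.na(matched_f)],
      compound_id = truth$compound_id[matched_f[!is.na(matched_f)]],
      stringsAsFactors = FALSE
    ),
    truth_matched = !is.na(matched_t)
  )
}
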