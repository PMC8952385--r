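# Shared fixtures, all built in code at test time.

# Small, fast generator configuration for unit tests.
small_synth_cfg <- function(seed = 7, ...) {
  synth_config(seed = seed, rt_span = 240, n_gaussian = 8, n_distorted = 5,
               n_subthreshold = 1, ...)
}

# Hand-built deterministic run: a single Gaussian trace over a flat
# baseline-free grid, optionally with one MS2 trigger on the rising edge.
# No RNG: every value is explicit, so tests can assert exactly.
gaussian_run <- function(mz0 = 200.0, rt0 = 60, height = 1e5, sigma = 3,
                         cycle = 1, rt_span = 120, baseline = NULL,
                         ms2_at_frac = NULL, extra_points = NULL) {
  times <- seq(0, rt_span, by = cycle)
  spectra <- list()
  scan_no <- 0L
  for (t in times) {
    mzv <- numeric(0); inv <- numeric(0)
    peak <- height * exp(-(t - rt0)^2 / (2 * sigma^2))
    if (peak >= 1) { mzv <- mz0; inv <- peak }
    if (!is.null(baseline)) {
      mzv <- c(mzv, baseline$mz); inv <- c(inv, baseline$intensity)
    }
    if (!is.null(extra_points)) {
      sel <- abs(extra_points$rt - t) < cycle / 2
      if (any(sel)) { mzv <- c(mzv, extra_points$mz[sel]); inv <- c(inv, extra_points$intensity[sel]) }
    }
    o <- order(mzv)
    spectra[[length(spectra) + 1L]] <- list(
      scan_index = scan_no, ms_level = 1L, rt = t,
      mz = mzv[o], intensity = inv[o],
      precursor_mz = NA_real_, precursor_intensity = NA_real_,
      precursor_scan_index = NA_integer_
    )
    ms1_no <- scan_no
    scan_no <- scan_no + 1L
    if (!is.null(ms2_at_frac) && peak >= 1 && t < rt0 &&
        peak >= ms2_at_frac[1] * height && peak <= ms2_at_frac[2] * height) {
      spectra[[length(spectra) + 1L]] <- list(
        scan_index = scan_no, ms_level = 2L, rt = t + cycle / 2,
        mz = c(80, 120), intensity = c(100, 50),
        precursor_mz = mz0, precursor_intensity = peak,
        precursor_scan_index = ms1_no
      )
      scan_no <- scan_no + 1L
      ms2_at_frac <- NULL # only one trigger
    }
  }
  new_run(spectra, sample_id = "fixture")
}

# Exhaustive O(n^2)-style oracle for precursor deduplication: repeatedly
# take the most intense remaining precursor and absorb everything in its
# window. Independent of the implementation's data path.
dedupe_oracle <- function(df, mz_tol, rt_tol) {
  df <- df[order(-df$intensity, df$mz, df$rt), , drop = FALSE]
  kept <- df[0, ]
  while (nrow(df) > 0L) {
    top <- df[1, , drop = FALSE]
    kept <- rbind(kept, top)
    absorb <- abs(df$mz - top$mz) <= mz_tol & abs(df$rt - top$rt) <= rt_tol
    df <- df[!absorb, , drop = FALSE]
  }
  kept[order(kept$mz, kept$rt), , drop = FALSE]
}

# Direct evaluation of the weighted dot-product formula over an explicit
# matching; used with exhaustive matchings for small spectra.
dot_product_formula <- function(a, b, pairs, ip = 0.5, mp = 0) {
  wa <- a[, 2]^ip * a[, 1]^mp
  wb <- b[, 2]^ip * b[, 1]^mp
  num <- if (nrow(pairs)) sum(wa[pairs[, 1]] * wb[pairs[, 2]]) else 0
  num^2 / (sum(wa^2) * sum(wb^2))
}

# Best achievable score over all one-to-one matchings within tol
# (exhaustive; for spectra of <= 6 fragments).
dot_product_oracle <- function(a, b, tol, ip = 0.5, mp = 0) {
  na <- nrow(a); nb <- nrow(b)
  best <- 0
  rec <- function(i, used_b, pairs) {
    if (i > na) {
      sc <- dot_product_formula(a, b, pairs, ip, mp)
      if (sc > best) best <<- sc
      return(invisible())
    }
    rec(i + 1L, used_b, pairs) # leave fragment i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(a[i, 1] - b[j, 1]) <= tol) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, rbind(pairs, c(i, j)))
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), matrix(integer(0), 0, 2))
  best
}

ppm_diff_test <- function(a, b) abs(a - b) / ((a + b) / 2) * 1e6

# scan_index of the first MS2 scan in a run
ms2_scan_of <- function(run) {
  lev <- vapply(run$spectra, function(s) s$ms_level, integer(1))
  which(lev == 2L)[1] - 1L
}

# Canonical small feature table exercising every serialized column.
as_features_for_test <- function() {
  data.frame(
    feature_id = c("PP0001", "MR0001", "TL0001"),
    mz = c(180.0634, 268.1041, 304.0912),
    rt = c(120.5, 241, 302.25),
    rtmin = c(112, 237, 298),
    rtmax = c(130, 246, 308),
    intensity = c(150000, 4200, 900.5),
    area = c(1.2e6, 21000, 5400),
    source = c("PP", "MR", "TL"),
    ms2_scan = c(45L, 210L, NA),
    sn = c(1500, 42, 9.5),
    stringsAsFactors = FALSE
  )
}

# Minimal run wrapping a precursor list: two MS1 anchor scans plus one MS2
# scan per precursor. Fast enough for hundreds of oracle instances.
mini_precursor_run <- function(df, rt_max = 130) {
  spectra <- list(
    list(scan_index = 0L, ms_level = 1L, rt = 0, mz = 100, intensity = 1,
         precursor_mz = NA_real_, precursor_intensity = NA_real_,
         precursor_scan_index = NA_integer_),
    list(scan_index = 1L, ms_level = 1L, rt = rt_max, mz = 100, intensity = 1,
         precursor_mz = NA_real_, precursor_intensity = NA_real_,
         precursor_scan_index = NA_integer_)
  )
  for (i in seq_len(nrow(df))) {
    spectra[[length(spectra) + 1L]] <- list(
      scan_index = length(spectra), ms_level = 2L, rt = df$rt[i],
      mz = c(60, 80), intensity = c(5, 3),
      precursor_mz = df$mz[i], precursor_intensity = df$intensity[i],
      precursor_scan_index = 0L
    )
  }
  new_run(spectra)
}

# Independent greedy nearest-m/z matcher + direct formula evaluation, used
# as the dot_product oracle for exact agreement checks.
greedy_dot_oracle <- function(a, b, tol, ip = 0.5, mp = 0) {
  wa <- a[, 2]^ip * a[, 1]^mp
  wb <- b[, 2]^ip * b[, 1]^mp
  cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  cand$d <- abs(a[cand$i, 1] - b[cand$j, 1])
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d, -(wa[cand$i] * wb[cand$j])), , drop = FALSE]
  ua <- logical(nrow(a)); ub <- logical(nrow(b)); num <- 0
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!ua[i] && !ub[j]) { ua[i] <- TRUE; ub[j] <- TRUE; num <- num + wa[i] * wb[j] }
  }
  num^2 / (sum(wa^2) * sum(wb^2))
}

msp_fixture_path <- function() {
  system.file("extdata", "synthetic_library.msp", package = "peakrescue")
}
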