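# Build a run whose MS2 scans are explicit, for precise precursor tests.
precursor_run <- function(precursors, rt_span = 300) {
  spectra <- list()
  scan_no <- 0L
  for (t in seq(0, rt_span, by = 1)) {
    spectra[[length(spectra) + 1L]] <- list(
      scan_index = scan_no, ms_level = 1L, rt = t,
      mz = 500.0, intensity = 150,
      precursor_mz = NA_real_, precursor_intensity = NA_real_,
      precursor_scan_index = NA_integer_
    )
    scan_no <- scan_no + 1L
    sel <- which(abs(precursors$rt - t) < 0.5)
    for (i in sel) {
      spectra[[length(spectra) + 1L]] <- list(
        scan_index = scan_no, ms_level = 2L, rt = t + 0.5,
        mz = c(60, 80), intensity = c(10, 5),
        precursor_mz = precursors$mz[i],
        precursor_intensity = precursors$intensity[i],
        precursor_scan_index = scan_no - 1L
      )
      scan_no <- scan_no + 1L
    }
  }
  new_run(spectra)
}

test_that("dedupe_precursors keeps the most intense precursor per window", {
  run <- precursor_run(data.frame(
    mz = c(200.0000, 200.0050), rt = c(100, 110), intensity = c(500, 900)))
  out <- dedupe_precursors(run)
  expect_equal(nrow(out), 1L)
  expect_equal(out$intensity, 900)
  expect_equal(out$mz, 200.0050)

  # 0.02 Da apart at the same RT: outside the window, both kept
  run <- precursor_run(data.frame(
    mz = c(200.00, 200.02), rt = c(100, 100), intensity = c(500, 900)))
  expect_equal(nrow(dedupe_precursors(run)), 2L)

  # a single precursor is returned unchanged
  run <- precursor_run(data.frame(mz = 300.05, rt = 50, intensity = 777))
  out <- dedupe_precursors(run)
  expect_equal(out$mz, 300.05)
  expect_equal(out$rt, 50.5) # MS2 scan RT
  expect_equal(out$intensity, 777)
})

test_that("dedupe_precursors matches the exhaustive clustering oracle", {
  cfg <- mr_config()
  withr::with_seed(99, {
    for (rep in 1:25) {
      n <- sample(1:50, 1)
      df <- data.frame(
        mz = round(runif(n, 200, 200.06), 4),
        rt = round(runif(n, 0, 120)),
        intensity = round(runif(n, 10, 1000))
      )
      # distinct intensities keep the greedy order unambiguous
      df$intensity <- df$intensity + seq_len(n) * 1e-3
      run <- precursor_run(df, rt_span = 130)
      got <- dedupe_precursors(run, cfg)
      want <- dedupe_oracle(
        data.frame(mz = df$mz, rt = df$rt + 0.5, intensity = df$intensity),
        cfg$dedup_mz_tol, cfg$dedup_rt_tol)
      expect_equal(got$mz, want$mz)
      expect_equal(got$intensity, want$intensity)
    }
  })
})

test_that("filter_novel drops candidates explained by picked features", {
  cand <- data.frame(mz = 200.000, rt = 100, intensity = 500, ms2_scan = 5L)
  pp1 <- data.frame(mz = 200.004, rt = 130, intensity = 1, source = "PP")
  expect_equal(nrow(filter_novel(cand, as_features(pp1))), 0L)
  pp2 <- data.frame(mz = 200.020, rt = 100, intensity = 1, source = "PP")
  expect_equal(nrow(filter_novel(cand, as_features(pp2))), 1L)
  expect_identical(filter_novel(cand, empty_features()), cand)
})

test_that("extract_eic reproduces an injected trace and handles empty windows", {
  run <- gaussian_run(mz0 = 250, rt0 = 60, height = 5e4, sigma = 3)
  eic <- extract_eic(run, 250, 0.01, 60, 15)
  expect_equal(nrow(eic), 31L)
  expect_equal(max(eic$intensity), 5e4)
  truth <- 5e4 * exp(-(eic$rt - 60)^2 / 18)
  expect_equal(eic$intensity, ifelse(truth >= 1, truth, 0), tolerance = 1e-9)

  far <- extract_eic(run, 400, 0.01, 60, 15)
  expect_true(all(far$intensity == 0))
  expect_equal(nrow(extract_eic(run, 250, 0.01, 1e5, 10)), 0L)
})

test_that("relocate_to_apex moves a flank trigger to the true apex", {
  run <- gaussian_run(mz0 = 250, rt0 = 60, height = 1e5, sigma = 3,
                      ms2_at_frac = c(0.3, 0.5))
  scan <- ms2_scan_of(run)
  sp <- run$spectra[[scan + 1L]]
  expect_lt(sp$precursor_intensity, 0.55 * 1e5) # triggered on the flank
  cand <- data.frame(mz = sp$precursor_mz, rt = sp$rt,
                     intensity = sp$precursor_intensity, ms2_scan = scan)
  rel <- relocate_to_apex(run, cand)
  expect_equal(rel$intensity, 1e5)
  expect_equal(rel$rt, 60)
  expect_identical(rel$ms2_scan, scan)

  # trigger already at apex: unchanged
  at_apex <- data.frame(mz = 250, rt = 60, intensity = 1e5, ms2_scan = scan)
  rel2 <- relocate_to_apex(run, at_apex)
  expect_equal(rel2$rt, 60)
  expect_equal(rel2$intensity, 1e5)

  # nothing in the window: apex-not-found error
  none <- data.frame(mz = 800, rt = 60, intensity = 10, ms2_scan = scan)
  expect_error(relocate_to_apex(run, none), class = "peakrescue_apex_not_found")
})

test_that("estimate_local_noise follows the median/fallback rules", {
  eic <- data.frame(scan_index = 0:9, rt = 0:9,
                    intensity = c(100, 100, 100, 100, 100, 5000, 100, 100, 100, 100))
  expect_equal(estimate_local_noise(eic, c(4.5, 5.5), floor = 100), 100)
  eic$intensity <- c(80, 90, 100, 110, 120, 5000, 0, 0, 0, 0)
  expect_equal(estimate_local_noise(eic, c(4.5, 5.5), floor = 10), 100)
  eic$intensity <- c(0, 0, 0, 50, 60, 5000, 0, 0, 0, 0)  # 2 nonzero points
  expect_equal(estimate_local_noise(eic, c(4.5, 5.5), floor = 100), 100)
})

test_that("validate_feature enforces noise-fold and consecutive-scan rules", {
  mk_run <- function(apex, n_scans) {
    pts <- data.frame(rt = seq(50, by = 1, length.out = n_scans),
                      mz = 300.0, intensity = apex * 0.8)
    pts$intensity[ceiling(n_scans / 2)] <- apex
    base <- data.frame(mz = 300.02, intensity = 100) # outside the m/z window
    gaussian_run(height = 0, rt_span = 120, baseline = base, extra_points = pts)
  }
  cand <- function(run, apex) {
    at <- which.max(vapply(run$spectra[run$ms1_index + 1L], function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)))
    data.frame(mz = 300.0, rt = 50 + at - 1, intensity = apex,
               ms2_scan = 1L, apex_scan = run$ms1_index[at])
  }
  run <- mk_run(400, 6)
  v <- validate_feature(run, cand(run, 400), mr_config())
  expect_true(v$valid)
  expect_equal(v$feature$source, "MR")
  expect_equal(v$feature$intensity, 400)
  expect_equal(v$noise, 100)

  run <- mk_run(250, 6)
  v <- validate_feature(run, cand(run, 250), mr_config())
  expect_false(v$valid)
  expect_equal(v$reason, "noise_fail")

  run <- mk_run(400, 3)
  v <- validate_feature(run, cand(run, 400), mr_config())
  expect_false(v$valid)
  expect_equal(v$reason, "consecutive_fail")
})

test_that("run_mr rescues distorted peaks and honors disjointness", {
  cfg <- synth_config(seed = 5, rt_span = 400, n_gaussian = 12, n_distorted = 6,
                      n_subthreshold = 0)
  res <- generate_run(cfg)
  pp <- pick_peaks(res$run)
  mr <- run_mr(res$run, pp)
  expect_gt(nrow(mr), 0L)
  # disjointness from PP within (0.01 Da, 60 s)
  for (i in seq_len(nrow(mr))) {
    expect_false(any(abs(pp$mz - mr$mz[i]) <= 0.01 & abs(pp$rt - mr$rt[i]) <= 60))
  }
  # every MR feature re-passes the noise and consecutive-scan assertions
  mcfg <- mr_config()
  for (i in seq_len(nrow(mr))) {
    eic <- extract_eic(res$run, mr$mz[i], mcfg$confirm_mass_tol, mr$rt[i],
                       mcfg$confirm_rt_tol)
    at <- which.min(abs(eic$rt - mr$rt[i]))
    nz <- eic$intensity > 0
    expect_true(nz[at])
    len <- 1L; j <- at
    while (j > 1L && nz[j - 1L]) { len <- len + 1L; j <- j - 1L }
    j <- at
    while (j < length(nz) && nz[j + 1L]) { len <- len + 1L; j <- j + 1L }
    expect_gte(len, mcfg$min_consecutive_scans)
    noise <- estimate_local_noise(eic, c(mr$rtmin[i], mr$rtmax[i]),
                                  floor = mcfg$noise_floor)
    expect_gt(mr$intensity[i], mcfg$noise_fold * noise)
    # apex dominance over the recorded trigger intensity
    sp <- res$run$spectra[[mr$ms2_scan[i] + 1L]]
    expect_gte(mr$intensity[i], sp$precursor_intensity - 1e-9)
  }
  # no MS2 scans at all -> no MR features
  ms1_only <- new_run(res$run$spectra[res$run$ms1_index + 1L])
  expect_equal(nrow(run_mr(ms1_only, pp)), 0L)
})

test_that("decreasing noise_fold never decreases the MR feature count", {
  res <- generate_run(small_synth_cfg(seed = 13))
  pp <- pick_peaks(res$run)
  n_prev <- -1L
  for (fold in c(10, 5, 3, 1)) {
    n <- nrow(run_mr(res$run, pp, mr_config(noise_fold = fold)))
    if (n_prev >= 0L) expect_gte(n, n_prev)
    n_prev <- n
  }
})
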