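test_that("detect_rois: single trace, prefilter, and ppm separation", {
  # one constant trace at m/z 200 across 12 scans
  pts <- data.frame(rt = rep(10:21, each = 1), mz = 200.0, intensity = 1e4)
  run <- gaussian_run(height = 0, rt_span = 30, extra_points = pts)
  rois <- detect_rois(run)
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$mz_center, 200, tolerance = 1e-6)
  expect_equal(nrow(rois[[1]]$trace), 12L)

  # all intensities below the prefilter threshold -> no ROI
  pts$intensity <- 50
  run <- gaussian_run(height = 0, rt_span = 30, extra_points = pts)
  expect_length(detect_rois(run), 0L)

  # two traces 50 ppm apart with 10 ppm tolerance -> two ROIs
  pts2 <- rbind(
    data.frame(rt = 10:21, mz = 200.0000, intensity = 1e4),
    data.frame(rt = 10:21, mz = 200.0100, intensity = 2e4)
  )
  run <- gaussian_run(height = 0, rt_span = 30, extra_points = pts2)
  rois <- detect_rois(run)
  expect_length(rois, 2L)
  # brute-force check: every trace point within tolerance of its center
  for (roi in rois) {
    expect_true(all(ppm_diff_test(roi$trace$mz, roi$mz_center) <= 10))
  }
})

test_that("pick_peaks recovers a clean Gaussian and respects filters", {
  run <- gaussian_run(mz0 = 200, rt0 = 60, height = 1e5, sigma = 3)
  ft <- pick_peaks(run)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$source, "PP")
  expect_lt(abs(ft$rt - 60), 1 + 1e-9)             # within one MS1 cycle
  expect_lt(abs(ft$intensity - 1e5) / 1e5, 0.05)   # apex within 5%
  expect_equal(ft$mz, 200, tolerance = 1e-4)

  # flat baseline only: nothing to pick
  base <- data.frame(mz = 300.0, intensity = 120)
  flat <- gaussian_run(height = 0, rt_span = 60, baseline = base)
  expect_equal(nrow(pick_peaks(flat)), 0L)

  # FWHM 2 s < peakwidth_min 5 s: rejected by the width filter
  narrow <- gaussian_run(mz0 = 200, rt0 = 60, height = 1e5, sigma = 2 / 2.355)
  expect_equal(nrow(pick_peaks(narrow)), 0L)
})

test_that("apex intensity equals the trace maximum inside [rtmin, rtmax]", {
  res <- generate_run(small_synth_cfg())
  ft <- pick_peaks(res$run)
  expect_gt(nrow(ft), 0L)
  for (i in seq_len(nrow(ft))) {
    eic <- extract_eic(res$run, ft$mz[i], 0.01,
                       (ft$rtmin[i] + ft$rtmax[i]) / 2,
                       (ft$rtmax[i] - ft$rtmin[i]) / 2 + 1e-9)
    expect_equal(ft$intensity[i], max(eic$intensity))
  }
})

test_that("pick_peaks is deterministic and duplicate-free on seeded runs", {
  res <- generate_run(small_synth_cfg(seed = 21))
  ft1 <- pick_peaks(res$run)
  ft2 <- pick_peaks(res$run)
  expect_identical(ft1, ft2)
  expect_false(is.unsorted(ft1$mz))
  # no two features within (mzdiff, peakwidth_min) of each other
  if (nrow(ft1) > 1L) {
    for (i in seq_len(nrow(ft1) - 1L)) {
      for (j in (i + 1L):nrow(ft1)) {
        expect_false(abs(ft1$mz[i] - ft1$mz[j]) < 0.01 &&
                     abs(ft1$rt[i] - ft1$rt[j]) < 5)
      }
    }
  }
})

test_that("well-formed Gaussian peaks are recalled at >= 95% (seeded)", {
  hits <- 0L; total <- 0L
  for (seed in c(101, 202, 303)) {
    cfg <- synth_config(seed = seed, rt_span = 300, n_gaussian = 12,
                        n_distorted = 0, n_subthreshold = 0,
                        height_range = c(5e3, 2e5)) # S/N >= 10 at noise 100
    res <- generate_run(cfg)
    ft <- pick_peaks(res$run)
    sc <- score_extraction(ft, res$truth)
    hits <- hits + sum(sc$truth_matched)
    total <- total + nrow(res$truth)
  }
  expect_gte(hits / total, 0.95)
})

test_that("lowering snthresh never decreases the feature count", {
  res <- generate_run(small_synth_cfg(seed = 33))
  n_prev <- -1L
  for (sn in c(10, 5, 3, 1)) {
    n <- nrow(pick_peaks(res$run, pp_config(snthresh = sn)))
    if (n_prev >= 0L) expect_gte(n, n_prev)
    n_prev <- n
  }
})
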