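mk_feat <- function(mz, rt, intensity = 1e4, source = "PP") {
  as_features(data.frame(mz = mz, rt = rt, intensity = intensity,
                         rtmin = rt - 5, rtmax = rt + 5, source = source))
}

test_that("group_features applies the minfrac/minsamp rule", {
  # same feature in 3 of 4 samples: 3 >= ceiling(0.5 * 4), kept
  tabs <- list(
    A = mk_feat(200.001, 100), B = mk_feat(200.002, 102),
    C = mk_feat(200.000, 99), D = mk_feat(350.5, 200)
  )
  grp <- group_features(tabs)
  expect_equal(nrow(grp$groups), 1L)
  expect_equal(grp$groups$mz_med, 200.001, tolerance = 1e-6)
  expect_equal(sum(!is.na(grp$intensities[1, ])), 3L)

  # feature in only 1 of 4 samples: dropped
  tabs <- list(A = mk_feat(200.001, 100), B = mk_feat(300.1, 50),
               C = mk_feat(400.2, 60), D = mk_feat(500.3, 70))
  expect_equal(nrow(group_features(tabs)$groups), 0L)

  # two features 0.03 Th apart (> mzwid) at the same RT: two groups
  tabs <- list(A = mk_feat(c(200.00, 200.03), c(100, 100)),
               B = mk_feat(c(200.00, 200.03), c(101, 101)))
  grp <- group_features(tabs)
  expect_equal(nrow(grp$groups), 2L)
})

test_that("group count is invariant to sample input order", {
  res <- lapply(c(1, 2, 3), function(k)
    generate_run(small_synth_cfg(seed = 77), sample_id = paste0("S", k),
                 run_seed = 700 + k))
  tabs <- lapply(res, function(r) pick_peaks(r$run))
  names(tabs) <- c("S1", "S2", "S3")
  g1 <- group_features(tabs)
  g2 <- group_features(rev(tabs))
  expect_equal(nrow(g1$groups), nrow(g2$groups))
  expect_equal(g1$groups$mz_med, g2$groups$mz_med)
  expect_equal(g1$intensities, g2$intensities)
})

test_that("shared injected features form exactly one group each (seeded)", {
  cfg <- synth_config(seed = 55, rt_span = 300, n_gaussian = 10,
                      n_distorted = 0, n_subthreshold = 0,
                      height_range = c(5e3, 2e5))
  runs <- lapply(1:3, function(k)
    generate_run(cfg, sample_id = paste0("S", k), run_seed = 550 + k))
  tabs <- lapply(runs, function(r) pick_peaks(r$run))
  names(tabs) <- paste0("S", 1:3)
  grp <- group_features(tabs)
  truth <- runs[[1]]$truth
  n_matched_once <- 0L
  for (i in seq_len(nrow(truth))) {
    hits <- sum(abs(grp$groups$mz_med - truth$mz[i]) <= 0.01 &
                abs(grp$groups$rt_med - truth$rt[i]) <= 10)
    if (hits == 1L) n_matched_once <- n_matched_once + 1L
  }
  expect_gte(n_matched_once / nrow(truth), 0.95)
})

test_that("gap_fill completes every cell and recovers sub-threshold signal", {
  # S1/S2 detect the peak; S3 has it injected below the picking threshold
  mk_run_height <- function(h) gaussian_run(mz0 = 220, rt0 = 60, height = h,
                                            sigma = 3, rt_span = 120)
  runs <- list(S1 = mk_run_height(5e4), S2 = mk_run_height(4e4),
               S3 = mk_run_height(250))
  tabs <- lapply(runs, pick_peaks)
  expect_equal(nrow(tabs$S3), 0L)
  grp <- group_features(tabs)
  expect_equal(nrow(grp$groups), 1L)
  filled <- gap_fill(grp, runs)
  expect_false(anyNA(filled$intensities))
  expect_true(filled$filled[1, "S3"])
  expect_false(any(filled$filled[1, c("S1", "S2")]))
  expect_lt(abs(filled$intensities[1, "S3"] - 250) / 250, 0.10)

  # nothing at the location in a sample without signal -> 0
  runs$S3 <- gaussian_run(mz0 = 500, rt0 = 60, height = 5e4, rt_span = 120)
  tabs$S3 <- empty_features()
  grp <- group_features(tabs)
  filled <- gap_fill(grp, runs)
  expect_equal(unname(filled$intensities[1, "S3"]), 0)

  # no missing members: intensities unchanged, nothing flagged
  runs$S3 <- mk_run_height(4e4)
  tabs$S3 <- pick_peaks(runs$S3)
  grp <- group_features(tabs)
  filled <- gap_fill(grp, runs)
  expect_identical(filled$intensities, grp$intensities)
  expect_false(any(filled$filled))

  # missing run -> error
  expect_error(gap_fill(grp, runs[c("S1", "S2")]), class = "peakrescue_config")
})

test_that("aligned_table flattens groups with filled flags", {
  runs <- list(S1 = gaussian_run(mz0 = 220, rt0 = 60, height = 5e4, rt_span = 120),
               S2 = gaussian_run(mz0 = 220, rt0 = 60, height = 300, rt_span = 120))
  tabs <- list(S1 = pick_peaks(runs$S1), S2 = empty_features())
  grp <- gap_fill(group_features(tabs, align_config(minfrac = 0.5)), runs)
  tab <- aligned_table(grp)
  expect_named(tab, c("group_id", "mz_med", "rt_med", "source_summary",
                      "S1", "S2", "filled_flags"))
  expect_equal(tab$filled_flags, "S2")
  expect_match(tab$source_summary, "PP:1")
})
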