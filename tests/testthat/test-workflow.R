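wf_samples <- function(n = 2, seed = 31, ...) {
  cfg <- synth_config(seed = seed, rt_span = 200, n_gaussian = 6,
                      n_distorted = 3, n_subthreshold = 0, ...)
  runs <- lapply(seq_len(n), function(k)
    generate_run(cfg, sample_id = paste0("S", k), run_seed = seed * 100 + k))
  out <- lapply(runs, `[[`, "run")
  names(out) <- paste0("S", seq_len(n))
  list(runs = out, truth = runs[[1]]$truth)
}

test_that("full mode produces per-sample tables, aligned table and outputs", {
  s <- wf_samples(2)
  out_dir <- withr::local_tempdir()
  targets <- data.frame(name = "t1", mz = s$truth$mz[1], rt = s$truth$rt[1])
  cfg <- workflow_config(s$runs, mode = "full", out_dir = out_dir,
                         targets = targets,
                         library = read_msp(msp_fixture_path()))
  res <- run_workflow(cfg)
  expect_named(res$features, c("S1", "S2"))
  srcs <- unique(unlist(lapply(res$features, `[[`, "source")))
  expect_true(all(c("PP", "MR") %in% srcs))
  expect_gt(nrow(res$aligned), 0L)
  expect_false(anyNA(res$groups$intensities))
  expect_true(file.exists(file.path(out_dir, "S1_features.csv")))
  expect_true(file.exists(file.path(out_dir, "aligned_table.csv")))
  expect_true(file.exists(file.path(out_dir, "run_summary.json")))

  # tier precedence: at most one tier reports a given physical signal
  for (ft in res$features) {
    for (i in seq_len(nrow(ft))) {
      others <- ft[-i, ]
      expect_false(any(abs(others$mz - ft$mz[i]) <= 0.01 &
                       abs(others$rt - ft$rt[i]) <= 30))
    }
  }
})

test_that("pp_only mode yields no MR/TL features", {
  s <- wf_samples(1)
  cfg <- workflow_config(s$runs, mode = "pp_only")
  res <- run_workflow(cfg)
  expect_true(all(res$features$S1$source == "PP"))
})

test_that("tl_only requires a targeted list; full-scan input degrades gracefully", {
  s <- wf_samples(1)
  expect_error(workflow_config(s$runs, mode = "tl_only"),
               class = "peakrescue_config")

  # strip MS2 scans: full-scan data, MR reports 0 candidates, still completes
  run <- s$runs$S1
  ms1 <- new_run(run$spectra[run$ms1_index + 1L], sample_id = "S1")
  res <- run_workflow(workflow_config(list(S1 = ms1), mode = "full"))
  expect_equal(unname(res$log$S1["n_mr"]), 0)
  expect_gt(nrow(res$features$S1), 0L)
})

test_that("external_table_in reuses an external PP table and still rescues", {
  s <- wf_samples(1)
  pp <- pick_peaks(s$runs$S1)
  half <- pp[seq_len(floor(nrow(pp) / 2)), ] # external tool found fewer peaks
  res <- run_workflow(workflow_config(
    s$runs, mode = "external_table_in", feature_tables = list(S1 = half)))
  ft <- res$features$S1
  expect_true(any(ft$source == "MR"))
  # the dropped PP peaks come back through the rescue tier
  expect_gt(sum(ft$source == "MR"), 0L)
})

test_that("serial and concurrent execution give identical tables", {
  s <- wf_samples(2, seed = 47)
  r1 <- run_workflow(workflow_config(s$runs, mode = "full", parallel = FALSE))
  r2 <- run_workflow(workflow_config(s$runs, mode = "full", parallel = TRUE))
  expect_identical(r1$features, r2$features)
  expect_identical(r1$aligned, r2$aligned)
})

test_that("errors surface with the failing stage and clean up outputs", {
  out_dir <- file.path(withr::local_tempdir(), "wf")
  cfg <- workflow_config(list(S1 = "/nonexistent/file.mzML"),
                         mode = "full", out_dir = out_dir)
  expect_error(run_workflow(cfg), regexp = "\\[S1/read\\]")
  expect_length(list.files(out_dir), 0L)
})

test_that("config-file parsing and the CLI drive a workflow end to end", {
  tmp <- withr::local_tempdir()
  mz1 <- file.path(tmp, "a.mzML")
  cfg <- synth_config(seed = 3, rt_span = 120, n_gaussian = 4, n_distorted = 2,
                      n_subthreshold = 0, baseline_n = 20)
  generate_run(cfg, path = mz1)

  conf <- file.path(tmp, "wf.conf")
  writeLines(c(
    "# workflow configuration",
    "mode: full",
    paste0("samples.a: ", mz1),
    "pick.ppm: 10",
    "pick.snthresh: 3",
    "mr.confirm_rt_tol: 60"
  ), conf)
  parsed <- read_workflow_config_file(conf)
  expect_equal(parsed$mode, "full")
  expect_equal(parsed$pick$ppm, 10)

  out <- file.path(tmp, "cli_out")
  expect_message(
    peakrescue_cli(c("run", "--config", conf, "--out", out)),
    "workflow complete")
  expect_true(file.exists(file.path(out, "a_features.csv")))
  ft <- read_feature_table(file.path(out, "a_features.csv"))
  expect_gt(nrow(ft), 0L)

  # simulate subcommand writes mzML + truth
  sim <- file.path(tmp, "sim.mzML"); tr <- file.path(tmp, "truth.csv")
  expect_message(
    peakrescue_cli(c("simulate", "--seed", "5", "--span", "120",
                     "--out", sim, "--truth", tr)),
    "wrote")
  expect_true(file.exists(sim) && file.exists(tr))
})
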