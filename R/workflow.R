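#' Workflow configuration
#'
#' Assembles the tiers into one of four workflow variants: `full`
#' (pick, rescue, then targeted extraction), `pp_only`, `tl_only`
#' (targeted extraction straight from raw data, also valid for
#' full-scan/DIA runs) and `external_table_in` (an externally produced
#' feature table replaces the picking tier, rescue/targeting still run).
#'
#' @param samples named list: sample_id -> mzML path or `ms_run` object.
#' @param mode workflow variant.
#' @param out_dir output directory; created if needed. `NULL` keeps all
#'   results in memory only.
#' @param targets targeted list (data.frame or CSV path); required for
#'   `tl_only`.
#' @param feature_tables named list sample_id -> feature table (data.frame
#'   or CSV path); required for `external_table_in`.
#' @param library MSP path or [read_msp()] result for annotation
#'   (optional).
#' @param dilutions named numeric vector (sample_id -> concentration);
#'   when present a PP-only vs joint LOD report is produced (requires
#'   `targets`).
#' @param pick,mr,tl,align,annotation per-module configurations.
#' @param parallel process samples concurrently with
#'   [parallel::mclapply()]; results are identical to serial execution.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(samples, mode = c("full", "pp_only", "tl_only",
                                              "external_table_in"),
                            out_dir = NULL, targets = NULL,
                            feature_tables = NULL, library = NULL,
                            dilutions = NULL,
                            pick = pp_config(), mr = mr_config(),
                            tl = tl_config(), align = align_config(),
                            annotation = annotation_config(),
                            parallel = FALSE) {
  mode <- match.arg(mode)
  if (length(samples) == 0L || is.null(names(samples)))
    stop_pr("samples must be a non-empty named list", "config")
  if (mode == "tl_only" && is.null(targets))
    stop_pr("mode 'tl_only' requires a targeted list", "config")
  if (mode == "external_table_in" &&
      (is.null(feature_tables) || !all(names(samples) %in% names(feature_tables))))
    stop_pr("mode 'external_table_in' requires a feature table per sample", "config")
  if (!is.null(dilutions) && is.null(targets))
    stop_pr("a dilution design requires a targeted list of compounds", "config")
  structure(as.list(environment()), class = "workflow_config")
}

load_run <- function(x, sample_id) {
  if (inherits(x, "ms_run")) return(x)
  read_mzml(x, sample_id = sample_id)
}

process_one_sample <- function(sid, cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_pr(sprintf("[%s/%s] %s", sid, name, conditionMessage(e)), "stage"))
  }
  run <- stage("read", load_run(cfg$samples[[sid]], sid))
  pp <- empty_features()
  if (cfg$mode %in% c("full", "pp_only")) {
    pp <- stage("pick", pick_peaks(run, cfg$pick,
                                   ms2_mass_tol = cfg$mr$confirm_mass_tol))
  } else if (cfg$mode == "external_table_in") {
    tab <- cfg$feature_tables[[sid]]
    pp <- stage("read_table", if (is.character(tab)) read_feature_table(tab)
                else as_features(tab, source = "PP"))
  }
  mr <- empty_features()
  if (cfg$mode %in% c("full", "external_table_in")) {
    mr <- stage("rescue", run_mr(run, pp, cfg$mr))
  }
  tl <- empty_features()
  if (!is.null(cfg$targets) && cfg$mode != "pp_only") {
    targets <- if (is.character(cfg$targets)) read_target_list(cfg$targets) else cfg$targets
    tl <- stage("target", run_tl(run, targets, rbind(pp, mr), cfg$tl))
  }
  features <- order_features(rbind(pp, mr, tl))
  list(sample_id = sid, run = run, features = features,
       log = c(n_pp = nrow(pp), n_mr = nrow(mr), n_tl = nrow(tl),
               attr(mr, "log")),
       mr_rejections = attr(mr, "rejections"),
       tl_report = attr(tl, "report"))
}

#' Run a complete workflow
#'
#' Per-sample feature extraction (according to the configured mode),
#' cross-sample grouping with gap filling, optional MS2 annotation and
#' optional PP-only vs joint LOD reporting. When `out_dir` is set, writes
#' per-sample feature tables, the aligned table, the annotation table, the
#' LOD report and a run-summary JSON; on error, partial outputs are
#' removed and the failing stage is named.
#'
#' @param cfg a [workflow_config()].
#' @return (invisibly) a list: `features` (per sample), `groups`,
#'   `aligned` (data.frame), `annotations`, `lod`, `log`.
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  out_dir <- cfg$out_dir
  written <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch(
    expr = {
      sids <- names(cfg$samples)
      apply_fun <- if (isTRUE(cfg$parallel)) {
        function(x, f) parallel::mclapply(x, f, mc.cores = min(2L, length(x)))
      } else lapply
      per_sample <- apply_fun(sids, function(s) process_one_sample(s, cfg))
      names(per_sample) <- sids
      for (ps in per_sample) if (inherits(ps, "try-error") || inherits(ps, "error"))
        stop_pr(conditionMessage(ps), "stage")

      tables <- lapply(per_sample, `[[`, "features")
      runs <- lapply(per_sample, `[[`, "run")
      grp <- group_features(tables, cfg$align)
      grp <- gap_fill(grp, runs, cfg$align, mass_tol = cfg$mr$confirm_mass_tol)
      aligned <- aligned_table(grp)

      annotations <- NULL
      if (!is.null(cfg$library)) {
        lib <- if (is.character(cfg$library)) read_msp(cfg$library) else cfg$library
        ann <- lapply(sids, function(s) {
          a <- annotate_features(tables[[s]], runs[[s]], lib, cfg$annotation)
          if (nrow(a)) cbind(sample_id = s, a, stringsAsFactors = FALSE) else NULL
        })
        annotations <- do.call(rbind, ann)
      }

      lod <- NULL
      if (!is.null(cfg$dilutions)) {
        targets <- if (is.character(cfg$targets)) read_target_list(cfg$targets) else cfg$targets
        pp_tabs <- lapply(tables, function(ft) ft[ft$source == "PP", , drop = FALSE])
        s_pp <- build_calibration_series(runs, pp_tabs, targets, cfg$dilutions,
                                         mass_tol = cfg$tl$mass_tol,
                                         rt_tol = cfg$tl$rt_tol,
                                         noise_floor = cfg$tl$noise_floor)
        s_joint <- build_calibration_series(runs, tables, targets, cfg$dilutions,
                                            mass_tol = cfg$tl$mass_tol,
                                            rt_tol = cfg$tl$rt_tol,
                                            noise_floor = cfg$tl$noise_floor)
        lod <- compare_lods(s_pp, s_joint)
      }

      logs <- lapply(per_sample, `[[`, "log")
      if (!is.null(out_dir)) {
        for (s in sids) {
          p <- file.path(out_dir, paste0(s, "_features.csv"))
          write_feature_table(tables[[s]], p); written <- c(written, p)
          rej <- per_sample[[s]]$mr_rejections
          if (!is.null(rej) && nrow(rej)) {
            p <- file.path(out_dir, paste0(s, "_mr_rejections.csv"))
            write.csv(rej, p, row.names = FALSE); written <- c(written, p)
          }
          tlr <- per_sample[[s]]$tl_report
          if (!is.null(tlr) && nrow(tlr)) {
            p <- file.path(out_dir, paste0(s, "_tl_report.csv"))
            write.csv(tlr, p, row.names = FALSE); written <- c(written, p)
          }
        }
        p <- file.path(out_dir, "aligned_table.csv")
        write_aligned_table(grp, p); written <- c(written, p)
        if (!is.null(annotations)) {
          p <- file.path(out_dir, "annotations.csv")
          write.csv(annotations, p, row.names = FALSE); written <- c(written, p)
        }
        if (!is.null(lod)) {
          p <- file.path(out_dir, "lod_report.csv")
          write.csv(lod, p, row.names = FALSE); written <- c(written, p)
        }
        p <- file.path(out_dir, "run_summary.json")
        jsonlite::write_json(list(mode = cfg$mode, samples = sids,
                                  n_groups = nrow(grp$groups),
                                  per_sample = logs),
                             p, auto_unbox = TRUE, pretty = TRUE)
        written <- c(written, p)
      }
      invisible(list(features = tables, groups = grp, aligned = aligned,
                     annotations = annotations, lod = lod, log = logs))
    },
    error = function(e) {
      unlink(written)
      stop(e)
    }
  )
}

#' Read a flat `key: value` workflow configuration file
#'
#' A minimal YAML-style dialect: one `key: value` per line, `#` comments,
#' dots namespace module parameters (`pick.ppm: 10`, `mr.rt_tol: 60`),
#' comma-separated values become vectors, `samples.<id>: <path>` declares
#' inputs.
#'
#' @param path config file path.
#' @return a named list of parsed values, grouped by module prefix.
#' @export
read_workflow_config_file <- function(path) {
  if (!file.exists(path)) stop_pr(paste0("file not found: ", path), "config")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (length(parts) && !anyNA(num)) num else parts
    ks <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(ks) == 1L) out[[ks]] <- parsed
    else out[[ks[1]]][[paste(ks[-1], collapse = ".")]] <- parsed
  }
  out
}
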