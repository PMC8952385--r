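#' LC-MS run containers and mzML input/output
#'
#' A run is an RT-ordered collection of centroided MS1/MS2 spectra from one
#' mzML file. Each spectrum is a list with fields `scan_index` (0-based
#' position in the run), `ms_level` (1 or 2), `rt` (always seconds),
#' `mz` / `intensity` (equal-length centroid vectors, m/z strictly
#' increasing), and for MS2 scans `precursor_mz`, `precursor_intensity` and
#' `precursor_scan_index` (0-based index of the parent MS1 scan, or `NA`).
#'
#' @param spectra list of spectrum lists (see Details).
#' @param sample_id sample identifier carried into downstream tables.
#' @return an object of class `ms_run`: a list with elements `sample_id`,
#'   `spectra` and `ms1_index` (0-based scan indices of MS1 scans in RT
#'   order).
#' @export
new_run <- function(spectra, sample_id = "sample") {
  if (length(spectra) == 0L) stop_pr("run contains no spectra", "empty_run")
  rt <- vapply(spectra, function(s) s$rt, numeric(1))
  lev <- vapply(spectra, function(s) as.integer(s$ms_level), integer(1))
  if (any(rt < 0)) stop_pr("negative retention time", "format")
  ord <- order(rt, seq_along(spectra))
  spectra <- spectra[ord]
  old_index <- vapply(spectra, function(s) {
    if (is.null(s$scan_index)) NA_integer_ else as.integer(s$scan_index)
  }, integer(1))
  for (i in seq_along(spectra)) {
    spectra[[i]]$scan_index <- i - 1L
    ref <- spectra[[i]]$precursor_scan_index
    if (!is.null(ref) && !is.na(ref)) {
      # remap parent reference from pre-sort indices
      pos <- match(as.integer(ref), old_index)
      spectra[[i]]$precursor_scan_index <- if (is.na(pos)) NA_integer_ else pos - 1L
    }
  }
  lev <- lev[ord]
  if (!any(lev == 1L)) stop_pr("run contains no MS1 scans", "empty_run")
  for (i in which(lev == 2L)) {
    if (is.null(spectra[[i]]$precursor_mz) || is.na(spectra[[i]]$precursor_mz))
      stop_pr("MS2 scan without precursor m/z", "format")
  }
  structure(
    list(sample_id = sample_id, spectra = spectra,
         ms1_index = which(lev == 1L) - 1L),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  n2 <- length(x$spectra) - length(x$ms1_index)
  rts <- range(vapply(x$spectra, function(s) s$rt, numeric(1)))
  cat(sprintf(
    "<ms_run> %s: %d spectra (%d MS1, %d MS2), RT %.1f-%.1f s\n",
    x$sample_id, length(x$spectra), length(x$ms1_index), n2, rts[1], rts[2]
  ))
  invisible(x)
}

ms1_rts <- function(run) {
  vapply(run$spectra[run$ms1_index + 1L], function(s) s$rt, numeric(1))
}

ms1_cycle_time <- function(run) {
  rts <- ms1_rts(run)
  if (length(rts) < 2L) return(1)
  median(diff(rts))
}

ms2_scans <- function(run) {
  idx <- setdiff(seq_along(run$spectra) - 1L, run$ms1_index)
  idx[vapply(run$spectra[idx + 1L], function(s) s$ms_level == 2L, logical(1))]
}

## ---- mzML reading -------------------------------------------------------

decode_binary_array <- function(node, ns, n_expected) {
  cv <- xml2::xml_find_all(node, "./d1:cvParam", ns)
  acc <- xml2::xml_attr(cv, "accession")
  raw <- jsonlite::base64_dec(gsub("\\s", "", xml2::xml_text(
    xml2::xml_find_first(node, "./d1:binary", ns)
  )))
  if ("MS:1000574" %in% acc) { # zlib
    raw <- tryCatch(memDecompress(raw, type = "gzip"),
                    error = function(e) stop_pr("cannot decompress zlib binary array", "format"))
  }
  size <- if ("MS:1000521" %in% acc) 4L else 8L # default 64-bit float
  vals <- readBin(raw, what = "double", n = length(raw) %/% size,
                  size = size, endian = "little")
  kind <- if ("MS:1000514" %in% acc) "mz" else if ("MS:1000515" %in% acc) "intensity" else "other"
  list(kind = kind, values = vals)
}

#' Read a centroided mzML file
#'
#' Reads MS1 and DDA MS2 scans. Retention times are converted to seconds
#' regardless of the file's unit attribute. Profile-mode spectra are
#' rejected. MS2 precursor intensities missing from the file are filled from
#' the nearest preceding MS1 scan within `fill_ppm` of the precursor m/z.
#'
#' @param path path to an mzML file.
#' @param sample_id sample identifier; defaults to the file name.
#' @param fill_ppm ppm tolerance used to back-fill missing precursor
#'   intensities from the parent MS1 scan.
#' @return an [new_run()] `ms_run` object.
#' @export
read_mzml <- function(path, sample_id = NULL, fill_ppm = 10) {
  if (!file.exists(path)) stop_pr(paste0("file not found: ", path), "format")
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_pr(paste0("not parseable as XML: ", path), "format"))
  ns <- c(d1 = xml2::xml_ns(doc)[[1]])
  nodes <- xml2::xml_find_all(doc, "//d1:spectrumList/d1:spectrum", ns)
  if (length(nodes) == 0L) stop_pr("mzML contains no spectra", "empty_run")
  if (is.null(sample_id)) sample_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)

  ids <- xml2::xml_attr(nodes, "id")
  spectra <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    s <- nodes[[i]]
    cv <- xml2::xml_find_all(s, "./d1:cvParam", ns)
    acc <- xml2::xml_attr(cv, "accession")
    val <- xml2::xml_attr(cv, "value")
    if ("MS:1000128" %in% acc)
      stop_pr("profile-mode spectrum found; centroid the data first", "format")
    ms_level <- as.integer(val[match("MS:1000511", acc)])
    if (is.na(ms_level)) ms_level <- 1L

    scan_cv <- xml2::xml_find_all(s, "./d1:scanList/d1:scan/d1:cvParam", ns)
    sacc <- xml2::xml_attr(scan_cv, "accession")
    rt <- NA_real_
    k <- match("MS:1000016", sacc)
    if (!is.na(k)) {
      rt <- as.numeric(xml2::xml_attr(scan_cv[[k]], "value"))
      unit <- xml2::xml_attr(scan_cv[[k]], "unitAccession")
      uname <- xml2::xml_attr(scan_cv[[k]], "unitName")
      if (identical(unit, "UO:0000031") || identical(uname, "minute")) rt <- rt * 60
    }
    if (is.na(rt)) stop_pr("spectrum without scan start time", "format")

    prec_mz <- prec_int <- NA_real_
    prec_ref <- NA_integer_
    if (ms_level == 2L) {
      pnode <- xml2::xml_find_first(s, "./d1:precursorList/d1:precursor", ns)
      if (!inherits(pnode, "xml_missing")) {
        picv <- xml2::xml_find_all(pnode, ".//d1:selectedIon/d1:cvParam", ns)
        pacc <- xml2::xml_attr(picv, "accession")
        pval <- xml2::xml_attr(picv, "value")
        prec_mz <- as.numeric(pval[match("MS:1000744", pacc)])
        j <- match("MS:1000042", pacc)
        if (!is.na(j)) prec_int <- as.numeric(pval[j])
        ref <- xml2::xml_attr(pnode, "spectrumRef")
        if (!is.na(ref)) {
          pos <- match(ref, ids)
          if (!is.na(pos)) prec_ref <- pos - 1L
        }
      }
      if (is.na(prec_mz)) stop_pr("MS2 scan without selected-ion m/z", "format")
    }

    arrs <- xml2::xml_find_all(s, "./d1:binaryDataArrayList/d1:binaryDataArray", ns)
    mzv <- numeric(0); inv <- numeric(0)
    for (a in arrs) {
      dec <- decode_binary_array(a, ns, NA)
      if (dec$kind == "mz") mzv <- dec$values
      if (dec$kind == "intensity") inv <- dec$values
    }
    if (length(mzv) != length(inv))
      stop_pr("m/z and intensity arrays differ in length", "format")
    if (is.unsorted(mzv)) {
      o <- order(mzv); mzv <- mzv[o]; inv <- inv[o]
    }
    spectra[[i]] <- list(
      scan_index = i - 1L, ms_level = ms_level, rt = rt,
      mz = mzv, intensity = inv,
      precursor_mz = prec_mz, precursor_intensity = prec_int,
      precursor_scan_index = prec_ref
    )
  }
  run <- new_run(spectra, sample_id = sample_id)
  fill_precursor_intensity(run, fill_ppm)
}

# Missing MS2 precursor intensities are looked up in the nearest preceding
# MS1 scan; the rescue tier re-derives apex intensity anyway.
fill_precursor_intensity <- function(run, ppm_tol = 10) {
  for (i in ms2_scans(run) + 1L) {
    sp <- run$spectra[[i]]
    if (!is.na(sp$precursor_intensity)) next
    parent <- sp$precursor_scan_index
    if (is.na(parent)) {
      prev <- run$ms1_index[run$ms1_index < sp$scan_index]
      if (length(prev) == 0L) next
      parent <- max(prev)
    }
    ms1 <- run$spectra[[parent + 1L]]
    tol <- sp$precursor_mz * ppm_tol * 1e-6
    sel <- which(ms1$mz >= sp$precursor_mz - tol & ms1$mz <= sp$precursor_mz + tol)
    run$spectra[[i]]$precursor_intensity <-
      if (length(sel)) max(ms1$intensity[sel]) else 0
  }
  run
}

## ---- mzML writing -------------------------------------------------------

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
}

#' Write a run to mzML
#'
#' Writes a minimal mzML 1.1 document: centroid spectra, 64-bit float
#' arrays, no compression, RT in seconds. Output bytes are a pure function
#' of the run contents, which underpins the generator's byte-determinism
#' contract.
#'
#' @param run an `ms_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$spectra)
  chunks <- character(n)
  for (i in seq_len(n)) {
    sp <- run$spectra[[i]]
    mode_cv <- '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
    lev_cv <- sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>', sp$ms_level)
    type_cv <- if (sp$ms_level == 1L)
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
    else
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
    scan <- sprintf(
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
      sp$rt
    )
    prec <- ""
    if (sp$ms_level == 2L) {
      ref <- if (!is.null(sp$precursor_scan_index) && !is.na(sp$precursor_scan_index))
        sprintf(' spectrumRef="scan=%d"', sp$precursor_scan_index + 1L) else ""
      pint <- if (!is.null(sp$precursor_intensity) && !is.na(sp$precursor_intensity))
        sprintf('<cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="%.4f"/>', sp$precursor_intensity) else ""
      prec <- sprintf(
        '<precursorList count="1"><precursor%s><selectedIonList count="1"><selectedIon><cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>%s</selectedIon></selectedIonList></precursor></precursorList>',
        ref, sp$precursor_mz, pint
      )
    }
    b_mz <- encode_doubles(sp$mz)
    b_in <- encode_doubles(sp$intensity)
    arr <- function(b64, acc, name) sprintf(
      paste0(
        '<binaryDataArray encodedLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
        '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
        '<binary>%s</binary></binaryDataArray>'
      ), nchar(b64), acc, name, b64
    )
    chunks[i] <- paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">', i - 1L, i, length(sp$mz)),
      lev_cv, type_cv, mode_cv, scan, prec,
      '<binaryDataArrayList count="2">',
      arr(b_mz, "MS:1000514", "m/z array"),
      arr(b_in, "MS:1000515", "intensity array"),
      "</binaryDataArrayList></spectrum>"
    )
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    "</cvList>\n",
    sprintf('<run id="%s">\n<spectrumList count="%d" defaultDataProcessingRef="dp">\n', run$sample_id, n),
    paste0(chunks, collapse = "\n"),
    "\n</spectrumList>\n</run>\n</mzML>\n"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(doc), con)
  invisible(path)
}
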