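# Reading and writing runs, manifests and tables.

#' Write a run as a centroid CSV
#'
#' The CSV dialect has columns `run_id`, `scan_rt_s`, `mz`,
#' `intensity`, one row per centroid.
#'
#' @param run A `cil_run`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_run_csv <- function(run, path) {
  dt <- data.table(run_id = attr(run, "run_id") %||% "run",
                   scan_rt_s = run$rt, mz = run$mz,
                   intensity = run$intensity)
  fwrite(dt, path)
  invisible(path)
}

#' Read a centroid CSV run
#'
#' @param path File written by [write_run_csv()].
#' @return A `cil_run`.
#' @export
read_run_csv <- function(path) {
  dt <- fread(path)
  need <- c("run_id", "scan_rt_s", "mz", "intensity")
  if (!all(need %in% names(dt))) {
    stop("not a centroid CSV (need columns ",
         paste(need, collapse = ", "), "): ", path)
  }
  run_id <- if (nrow(dt)) dt$run_id[1] else
    sub("\\.csv$", "", basename(path))
  cent <- dt[, .(rt = scan_rt_s, mz, intensity)]
  setorder(cent, rt, mz)
  .as_cil_run(cent, run_id, run_id, 1)
}

#' Write a run as centroided MS1 mzML
#'
#' Centroids are grouped by scan time into MS1 spectra (positive mode,
#' centroided flag set) and written through the `mzR` backend.
#'
#' @param run A `cil_run`.
#' @param path Output `.mzML` path.
#' @return The path, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package")
  }
  rts <- sort(unique(run$rt))
  peaks <- lapply(rts, function(t) {
    p <- run[J(t), on = "rt"][order(mz)]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  n <- length(rts)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(peaks, nrow, integer(1)),
    totIonCurrent = vapply(peaks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rts,
    basePeakMZ = vapply(peaks, function(p) p[which.max(p[, 2]), 1],
                        numeric(1)),
    basePeakIntensity = vapply(peaks, function(p) max(p[, 2]), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(peaks, function(p) min(p[, 1]), numeric(1)),
    highMZ = vapply(peaks, function(p) max(p[, 1]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(peaks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroided MS1 mzML run
#'
#' @param path An `.mzML` file.
#' @param run_id Run id to attach; defaults to the file stem.
#' @return A `cil_run`.
#' @export
read_run_mzml <- function(path, run_id = sub("\\.mzML$", "", basename(path),
                                             ignore.case = TRUE)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  ms1 <- which(hdr$msLevel == 1L)
  pk <- mzR::peaks(fh)
  if (!is.list(pk)) pk <- list(pk)
  cent <- rbindlist(lapply(ms1, function(i) {
    p <- pk[[i]]
    data.table(rt = hdr$retentionTime[i], mz = p[, 1], intensity = p[, 2])
  }))
  setorder(cent, rt, mz)
  .as_cil_run(cent, run_id, run_id, 1)
}

#' Read a run, dispatching on file extension
#'
#' `.csv` files use the centroid CSV dialect, `.mzML` files go through
#' mzR.
#'
#' @param path Run file path.
#' @return A `cil_run`.
#' @export
read_run <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) read_run_mzml(path)
  else read_run_csv(path)
}

#' Write the sample manifest of a design as CSV
#'
#' @param design A `cil_design`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest_csv <- function(design, path) {
  fwrite(design$manifest[, .(run_id, sample_id, arm, week, rat_index,
                             duplicate_index, role, treatment, group_id)],
         path)
  invisible(path)
}

#' Write the truth table of a simulated study as CSV
#'
#' One row per (sample, metabolite) with the true concentration and
#' ratio to the pool.
#'
#' @param truth A `cil_truth`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  out <- copy(truth$concentrations)
  setnames(out, "id", "metabolite_id")
  fwrite(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
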