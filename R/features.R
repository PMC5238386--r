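# Chromatographic feature (EIC peak) extraction.

#' Parameters of feature extraction and peak pairing
#'
#' @param mz_tol_ppm Pairing mass tolerance in ppm, applied relative
#'   to the light m/z with inclusive boundaries.
#' @param rt_coelution_tol Maximum apex retention-time difference (s)
#'   for two features to count as co-eluting.
#' @param n_tags_range Candidate dansyl tag counts.
#' @param sn_threshold Minimum apex height as a multiple of the
#'   run's estimated noise level.
#' @param min_scans Minimum number of supporting scans per feature.
#' @param eic_ppm Half-width (ppm) used to bin centroids into EIC
#'   traces across scans.
#' @param max_gap Number of empty scans tolerated inside a trace.
#' @param valley_frac A valley splits two peaks only if it falls below
#'   this fraction of the lower apex.
#' @param isotope_delta 13C-12C spacing used by the natural-isotope
#'   exclusion rule, Da.
#' @param scan_interval Scan spacing in seconds (areas are
#'   sum(intensity) x this interval).
#' @return A list of class `cil_pair_params`.
#' @export
pair_params <- function(mz_tol_ppm = 10, rt_coelution_tol = 10,
                        n_tags_range = 1:3, sn_threshold = 3,
                        min_scans = 4, eic_ppm = 10, max_gap = 1,
                        valley_frac = 0.5,
                        isotope_delta = 1.00335484,
                        scan_interval = 1) {
  stopifnot(mz_tol_ppm > 0, rt_coelution_tol > 0, all(n_tags_range >= 1),
            sn_threshold > 0, min_scans >= 1, eic_ppm > 0,
            valley_frac > 0, valley_frac <= 1, isotope_delta > 0,
            scan_interval > 0)
  structure(list(mz_tol_ppm = mz_tol_ppm,
                 rt_coelution_tol = rt_coelution_tol,
                 n_tags_range = as.integer(n_tags_range),
                 sn_threshold = sn_threshold, min_scans = min_scans,
                 eic_ppm = eic_ppm, max_gap = as.integer(max_gap),
                 valley_frac = valley_frac, isotope_delta = isotope_delta,
                 scan_interval = scan_interval),
            class = "cil_pair_params")
}

# Assign EIC trace ids to centroids sorted by m/z: a new trace starts
# wherever the gap between consecutive sorted m/z values exceeds the
# ppm tolerance.
.assign_traces <- function(mz_sorted, eic_ppm) {
  if (length(mz_sorted) == 0) return(integer(0))
  gap <- diff(mz_sorted) > eic_ppm * 1e-6 * mz_sorted[-1]
  cumsum(c(TRUE, gap))
}

# Number of distinct scans per trace, for centroids sorted so that
# equal (trace, scan) rows are adjacent.
.scans_per_trace <- function(trace, scan) {
  n <- length(trace)
  if (n == 0) return(integer(0))
  new_scan <- c(TRUE, trace[-1] != trace[-n] | scan[-1] != scan[-n])
  tabulate(trace[new_scan], nbins = max(trace))
}

# Noise level of a run: median intensity of centroids whose trace has
# too few scans to be a chromatographic peak (pure chemical noise).
.estimate_noise <- function(cent, params) {
  o <- order(cent$mz)
  mz <- cent$mz[o]
  trace <- .assign_traces(mz, params$eic_ppm)
  o2 <- order(trace, cent$rt[o])
  nsc <- .scans_per_trace(trace[o2], cent$rt[o][o2])
  noise_cent <- nsc[trace] < params$min_scans
  lvl <- median(cent$intensity[o][noise_cent])
  if (!is.finite(lvl)) lvl <- quantile(cent$intensity, 0.05, names = FALSE)
  if (!is.finite(lvl)) lvl <- 0
  lvl
}

#' Extract chromatographic features from a centroided run
#'
#' Centroids are binned into extracted-ion-chromatogram traces by a
#' ppm tolerance across scans; each trace is decomposed into peaks at
#' valleys between local maxima (allowing `max_gap` missing scans).
#' A peak is kept when its apex exceeds `sn_threshold` times the
#' run's estimated noise level and it spans at least `min_scans`
#' scans.  The noise level is the median intensity of centroids in
#' sub-`min_scans` traces (chemical noise); when a run contains no
#' such centroids the 5% intensity quantile is used.
#'
#' @param run A `cil_run` (or any data.frame with `rt`, `mz`,
#'   `intensity`).
#' @param params A [pair_params()].
#' @param min_height Absolute apex threshold in counts; overrides the
#'   S/N-derived threshold when given.
#' @return A `cil_features` object: list with `features` (one row per
#'   peak: `feature`, `mz`, `rt`, `rt_start`, `rt_end`, `height`,
#'   `area`, `n_scans`) and `centroids` (the trace-ordered centroid
#'   table with a `feature` column linking profile points to peaks).
#' @export
extract_features <- function(run, params = pair_params(),
                             min_height = NULL) {
  cent <- as.data.table(run)[, .(rt, mz, intensity)]
  if (nrow(cent) == 0) stop("empty run")

  setorder(cent, mz)
  cent[, trace := .assign_traces(mz, params$eic_ppm)]
  scan0 <- floor(min(cent$rt))
  cent[, scan := as.integer(round((rt - scan0) / params$scan_interval))]
  # traces are already ascending in the m/z order, so sorting by
  # (trace, scan) only reorders within traces
  setorder(cent, trace, scan, mz)

  if (is.null(min_height)) {
    nsc <- .scans_per_trace(cent$trace, cent$scan)
    noise <- median(cent$intensity[nsc[cent$trace] < params$min_scans])
    if (!is.finite(noise)) {
      noise <- quantile(cent$intensity, 0.05, names = FALSE)
    }
    min_height <- params$sn_threshold * noise
  }

  fx <- as.data.table(decompose_traces_cpp(
    cent$trace, cent$scan, cent$mz, cent$intensity,
    min_height, params$min_scans, params$max_gap, params$valley_frac))

  to_rt <- function(s) scan0 + s * params$scan_interval
  feats <- fx[, .(
    mz, rt = to_rt(scan_apex), rt_start = to_rt(scan_start),
    rt_end = to_rt(scan_end), height,
    area = area_raw * params$scan_interval, n_scans,
    idx_start, idx_end)]
  setorder(feats, mz)
  feats[, feature := seq_len(.N)]

  fcol <- rep(NA_integer_, nrow(cent))
  if (nrow(feats)) {
    len <- feats$idx_end - feats$idx_start + 1L
    fcol[sequence(len, from = feats$idx_start)] <-
      rep.int(feats$feature, len)
  }
  cent[, feature := fcol]

  structure(list(features = feats[], centroids = cent[],
                 noise_floor = min_height / params$sn_threshold,
                 params = params,
                 run_id = attr(run, "run_id")),
            class = "cil_features")
}

#' @export
print.cil_features <- function(x, ...) {
  cat("CIL features: ", nrow(x$features), " peaks from ",
      nrow(x$centroids), " centroids (run ",
      x$run_id %||% "?", ")\n", sep = "")
  invisible(x)
}
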