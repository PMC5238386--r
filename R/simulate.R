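# Emission of centroided MS1 runs from ground truth.

# Shared emitter: `spec` is a data.table with one row per metabolite
# (neutral_mass, n_tags, rt, response, conc_light, conc_heavy).
# Returns the centroid table of one run.
.emit_run <- function(spec, noise, rt_grid) {
  cc <- chem_constants()
  n <- nrow(spec)
  sig <- noise$peak_fwhm / (2 * sqrt(2 * log(2)))

  keep <- runif(n) >= noise$extra_dropout_prob
  spec <- spec[keep]
  n <- nrow(spec)
  if (n == 0) return(.empty_centroids())

  amp_l <- spec$response * spec$conc_light *
    rlnorm(n, 0, noise$intensity_sigma)
  amp_h <- spec$response * spec$conc_heavy *
    rlnorm(n, 0, noise$intensity_sigma)
  rt_c <- spec$rt + rnorm(n, 0, noise$rt_sd)
  mz_l <- labeled_mz(spec$neutral_mass, spec$n_tags, "light")
  mz_h <- mz_l + spec$n_tags * cc$tag_delta

  lo <- pmax(rt_grid[1], ceiling(rt_c - 4 * sig))
  hi <- pmin(rt_grid[length(rt_grid)], floor(rt_c + 4 * sig))
  cnt <- pmax(0L, as.integer(hi - lo + 1))
  idx <- rep.int(seq_len(n), cnt)
  tt <- unlist(lapply(seq_len(n), function(i) {
    if (cnt[i] > 0) seq(lo[i], hi[i]) else numeric(0)
  }))
  gauss <- exp(-(tt - rt_c[idx])^2 / (2 * sig^2))
  m <- length(tt)

  emit_channel <- function(mz0, amp) {
    int <- amp[idx] * gauss * rlnorm(m, 0, noise$scan_sigma)
    mz <- mz0[idx] * (1 + rnorm(m, 0, noise$mz_sd_ppm) * 1e-6)
    data.table(rt = tt, mz = mz, intensity = int, met = idx)
  }
  out <- list(emit_channel(mz_l, amp_l), emit_channel(mz_h, amp_h))

  if (noise$include_natural_isotopes) {
    # rough carbon count: metabolite skeleton plus 12 C per dansyl tag
    n_c <- round(spec$neutral_mass / 24) + 12 * spec$n_tags
    frac <- pmin(0.9, n_c * 0.011)
    iso <- function(ch) {
      s <- copy(ch)
      s[, intensity := intensity * frac[met]]
      s[, mz := mz + cc$c13_c12_spacing]
      s
    }
    out <- c(out, lapply(out, iso))
  }
  cent <- rbindlist(out)[, met := NULL][]

  if (noise$noise_peaks_per_scan > 0) {
    n_noise <- length(rt_grid) * noise$noise_peaks_per_scan
    mz_span <- range(c(mz_l, mz_h))
    cent <- rbind(cent, data.table(
      rt = sample(rt_grid, n_noise, replace = TRUE),
      mz = runif(n_noise, mz_span[1] - 20, mz_span[2] + 20),
      intensity = noise$detection_threshold * (1 + 0.6 * rexp(n_noise))
    ))
  }

  cent <- cent[intensity >= noise$detection_threshold]
  setorder(cent, rt, mz)
  cent[]
}

.empty_centroids <- function() {
  data.table(rt = numeric(0), mz = numeric(0), intensity = numeric(0))
}

.run_grid <- function(metabolome, noise) {
  r <- range(metabolome$metabolites$rt)
  seq(floor(r[1] - 30), ceiling(r[2] + 30), by = noise$scan_interval)
}

#' Simulate one centroided MS1 run of a 12C-sample / 13C-pool mixture
#'
#' Each detected metabolite yields a light peak at
#' `neutral_mass + n_tags * 233.05105 + 1.007276` and a heavy peak
#' `n_tags * 2.00671` Da higher, with Gaussian chromatographic
#' profiles sharing an apex and amplitudes proportional to the sample
#' (light) and pool (heavy) concentrations before noise.  QC runs
#' (`sample_id = "QC"`) mix pool against pool, so every true ratio is
#' exactly 1.  Centroids below the detection threshold are omitted.
#'
#' @param sample_id A sample id from the truth table, or `"QC"`.
#' @param truth A `cil_truth`.
#' @param metabolome The `cil_metabolome` the truth was drawn from.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seeds give identical centroids.
#' @param run_id Stored in the `run_id` attribute.
#' @return A `cil_run`: data.table of centroids (`rt`, `mz`,
#'   `intensity`) sorted by scan then m/z.
#' @export
simulate_run <- function(sample_id, truth, metabolome,
                         noise = noise_model(), seed = NULL,
                         run_id = sample_id) {
  if (!is.null(seed)) set.seed(seed)
  mets <- metabolome$metabolites[, .(id, neutral_mass, n_tags, rt, response)]
  mets <- merge(mets, truth$pool, by = "id", sort = FALSE)
  if (identical(sample_id, "QC")) {
    mets[, conc_light := pool_conc]
  } else {
    conc <- truth$concentrations[sample_id, on = "sample_id"]
    if (anyNA(conc$conc)) stop("unknown sample id: ", sample_id)
    mets <- merge(mets, conc[, .(id, conc)], by = "id", sort = FALSE)
    setnames(mets, "conc", "conc_light")
  }
  setnames(mets, "pool_conc", "conc_heavy")
  cent <- .emit_run(mets, noise, .run_grid(metabolome, noise))
  .as_cil_run(cent, run_id, sample_id, noise$scan_interval)
}

.as_cil_run <- function(cent, run_id, sample_id, scan_interval) {
  setattr(cent, "run_id", run_id)
  setattr(cent, "sample_id", sample_id)
  setattr(cent, "scan_interval", scan_interval)
  setattr(cent, "class", c("cil_run", class(cent)))
  cent
}

#' Simulate every injection of a study
#'
#' Draws one independent sub-seed per manifest row from the master
#' seed, so the whole set of runs is reproducible bit for bit.
#'
#' @param design A `cil_design`.
#' @param truth,metabolome,noise See [simulate_run()].
#' @param seed Master seed.
#' @param write_dir If non-NULL, each run is also written as a
#'   centroid CSV (`<run_id>.csv`) into this directory.
#' @return A named list of `cil_run` objects keyed by run id.
#' @export
simulate_study <- function(design, truth, metabolome,
                           noise = noise_model(), seed = 1,
                           write_dir = NULL) {
  manifest <- design$manifest
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, nrow(manifest))
  runs <- vector("list", nrow(manifest))
  names(runs) <- manifest$run_id
  for (i in seq_len(nrow(manifest))) {
    sid <- if (manifest$role[i] == "qc") "QC" else manifest$sample_id[i]
    runs[[i]] <- simulate_run(sid, truth, metabolome, noise,
                              seed = seeds[i], run_id = manifest$run_id[i])
    if (!is.null(write_dir)) {
      write_run_csv(runs[[i]], file.path(write_dir,
                                         paste0(manifest$run_id[i], ".csv")))
    }
  }
  runs
}

#' Simulate a single calibration run with known true ratios
#'
#' Convenience generator for accuracy benchmarks: plants one peak pair
#' per element of `true_ratios` (sample concentration =
#' `true_ratio`, pool concentration = 1) at random masses and
#' retention times, and emits one labeled run.
#'
#' @param true_ratios Numeric vector of true light/heavy ratios, one
#'   per planted pair.
#' @param noise A [noise_model()].
#' @param mass_range,rt_range Placement ranges.
#' @param response_meanlog,response_sdlog Lognormal response factors.
#' @param seed Integer seed.
#' @return A list with `run` (the `cil_run`) and `truth` (data.table
#'   of planted pairs: id, neutral_mass, n_tags, rt, true_ratio).
#' @export
simulate_ratio_run <- function(true_ratios, noise = noise_model(),
                               mass_range = c(80, 500),
                               rt_range = c(60, 1380),
                               response_meanlog = log(2e5),
                               response_sdlog = 0.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_ratios)
  spec <- data.table(
    id = sprintf("P%04d", seq_len(n)),
    neutral_mass = runif(n, mass_range[1], mass_range[2]),
    n_tags = sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
    rt = runif(n, rt_range[1], rt_range[2]),
    response = rlnorm(n, response_meanlog, response_sdlog),
    conc_light = true_ratios,
    conc_heavy = 1
  )
  grid <- seq(floor(rt_range[1] - 30), ceiling(rt_range[2] + 30),
              by = noise$scan_interval)
  cent <- .emit_run(copy(spec), noise, grid)
  run <- .as_cil_run(cent, "calibration", "calibration",
                     noise$scan_interval)
  list(run = run,
       truth = spec[, .(id, neutral_mass, n_tags, rt,
                        true_ratio = conc_light)])
}
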