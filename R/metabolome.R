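# Ground-truth metabolome and per-sample concentration simulation.

#' Simulate a ground-truth metabolome for a labeled study
#'
#' Draws `n_metabolites` dansylated metabolites with random neutral
#' masses, retention times, tag counts, base concentrations and MS
#' response factors, and assigns each a trajectory class that defines
#' how its concentration multiplier varies over the (arm, week) groups
#' of `design`:
#'
#' * `flat` - constant in every group.
#' * `oa_up` / `oa_down` - drifts up (down) in disease-bearing arms
#'   (the OA arm and all treatment arms) over weeks 0-6 and stays
#'   shifted; treatment does not reverse it.
#' * `random` - an independent lognormal fluctuation of the group mean
#'   in every (arm, week) group, emulating unmodeled biological drift.
#' * `treatment_reversing` - rises in disease arms to
#'   `biomarker_fold` at week 6, stays elevated in the untreated OA
#'   arm, and decays log-linearly back to the sham level by week 14 in
#'   every treatment arm.  Exactly `n_biomarkers` metabolites get this
#'   class; they are the planted markers the selection pipeline should
#'   recover.
#'
#' The disease ramp is log-interpolated through fractions 0, 0.65,
#' 0.9, 1 at weeks 0, 2, 4, 6 (a fast post-surgery response that
#' saturates by week 6).
#'
#' @param design A `cil_design`.
#' @param n_metabolites Total number of simulated metabolites.
#' @param n_biomarkers Number of planted treatment-reversing markers
#'   (`<= n_metabolites`).
#' @param mass_range,rt_range Ranges for neutral mass (Da) and
#'   retention time (s).
#' @param tag_probs Probabilities of 1, 2 and 3 dansyl tags.
#' @param class_probs Named probabilities for the non-planted classes
#'   `flat`, `oa_up`, `oa_down`, `random`.
#' @param biomarker_fold Week-6 fold change of the planted markers.
#' @param disease_fold_range Range of week-6 fold changes for
#'   `oa_up` metabolites (`oa_down` uses the reciprocal).
#' @param conc_sdlog,response_meanlog,response_sdlog Lognormal
#'   parameters of base concentrations and MS response factors.
#' @param random_sigma Lognormal sigma of the per-group drift of
#'   `random` metabolites.
#' @param library_compounds Optional data.table with `name`,
#'   `neutral_mass`, `tag_count`, `rt_s` (e.g.
#'   [load_dansyl_library()]); the first metabolites take their mass,
#'   tag count and retention time from it, so downstream annotation
#'   has identifiable rows.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `cil_metabolome`: list with `metabolites` (one row per
#'   metabolite) and `multipliers` (long table metabolite x group).
#' @export
simulate_metabolome <- function(design, n_metabolites = 300,
                                n_biomarkers = 11,
                                mass_range = c(80, 500),
                                rt_range = c(60, 1380),
                                tag_probs = c(0.8, 0.15, 0.05),
                                class_probs = c(flat = 0.70, oa_up = 0.10,
                                                oa_down = 0.10, random = 0.10),
                                biomarker_fold = 2,
                                disease_fold_range = c(1.5, 3),
                                conc_sdlog = 0.8,
                                response_meanlog = log(5e4),
                                response_sdlog = 1,
                                random_sigma = 0.10,
                                library_compounds = NULL,
                                seed = NULL) {
  if (n_biomarkers > n_metabolites) {
    stop("n_biomarkers must not exceed n_metabolites")
  }
  if (diff(range(mass_range)) <= 0) stop("empty mass range")
  if (!is.null(seed)) set.seed(seed)

  mets <- data.table(
    id = sprintf("M%04d", seq_len(n_metabolites)),
    neutral_mass = runif(n_metabolites, mass_range[1], mass_range[2]),
    n_tags = sample(1:3, n_metabolites, replace = TRUE, prob = tag_probs),
    rt = runif(n_metabolites, rt_range[1], rt_range[2]),
    base_conc = rlnorm(n_metabolites, 0, conc_sdlog),
    response = rlnorm(n_metabolites, response_meanlog, response_sdlog)
  )
  mets[, name := NA_character_]
  if (!is.null(library_compounds)) {
    lib <- as.data.table(library_compounds)
    k <- min(nrow(lib), n_metabolites)
    mets[seq_len(k), `:=`(neutral_mass = lib$neutral_mass[seq_len(k)],
                          n_tags = as.integer(lib$tag_count[seq_len(k)]),
                          rt = as.numeric(lib$rt_s[seq_len(k)]),
                          name = lib$name[seq_len(k)])]
  }
  cls <- sample(names(class_probs), n_metabolites, replace = TRUE,
                prob = class_probs)
  planted <- sample.int(n_metabolites, n_biomarkers)
  cls[planted] <- "treatment_reversing"
  mets[, trajectory_class := cls]
  mets[, amp := 1]
  mets[trajectory_class == "oa_up",
       amp := exp(runif(.N, log(disease_fold_range[1]),
                        log(disease_fold_range[2])))]
  mets[trajectory_class == "oa_down",
       amp := exp(-runif(.N, log(disease_fold_range[1]),
                         log(disease_fold_range[2])))]
  mets[trajectory_class == "treatment_reversing", amp := biomarker_fold]

  groups <- design$groups
  mult <- CJ(id = mets$id, group_id = groups$group_id, sorted = FALSE)
  mult <- merge(mult, mets[, .(id, trajectory_class, amp)], by = "id")
  mult <- merge(mult, groups[, .(group_id, arm, week, treatment)],
                by = "group_id")
  setorder(mult, id, group_id)

  diseased <- mult$arm == "OA" | mult$treatment != "none"
  ramp <- .disease_ramp(mult$week)
  revert <- ifelse(mult$treatment != "none" & mult$week >= 8,
                   pmax(0, (14 - mult$week) / 6), 1)

  logm <- numeric(nrow(mult))
  up <- mult$trajectory_class %in% c("oa_up", "oa_down")
  logm[up] <- (log(mult$amp) * ramp * diseased)[up]
  tr <- mult$trajectory_class == "treatment_reversing"
  logm[tr] <- (log(mult$amp) * ramp * revert * diseased)[tr]
  rnd <- mult$trajectory_class == "random"
  logm[rnd] <- rnorm(sum(rnd), 0, random_sigma)
  mult[, multiplier := exp(logm)]

  structure(list(metabolites = mets[],
                 multipliers = mult[, .(id, group_id, multiplier)]),
            class = "cil_metabolome")
}

# fraction of the final disease effect reached by a given week
.disease_ramp <- function(week) {
  w <- pmin(pmax(week, 0), 6)
  approx(c(0, 2, 4, 6), c(0, 0.65, 0.9, 1), xout = w)$y
}

#' @export
print.cil_metabolome <- function(x, ...) {
  cat("CIL metabolome:", nrow(x$metabolites), "metabolites (",
      sum(x$metabolites$trajectory_class == "treatment_reversing"),
      "planted treatment-reversing )\n")
  invisible(x)
}

#' Simulate per-sample true concentrations and ratios to the pool
#'
#' Every animal's concentration of each metabolite is its group-level
#' mean (base concentration times trajectory multiplier) perturbed by
#' lognormal biological variation.  The heavy-labeled pool is the
#' equal-mole mix of all study samples, so its concentration of each
#' metabolite is exactly the arithmetic mean over samples, and the
#' true ratio of a sample is its concentration divided by the pool's.
#'
#' @param metabolome A `cil_metabolome`.
#' @param design The `cil_design` it was simulated for.
#' @param biological_sigma Lognormal sigma of animal-to-animal
#'   variation.
#' @param seed Integer seed.
#' @return A `cil_truth`: list with `concentrations` (sample x
#'   metabolite long table with `conc` and `true_ratio`), `pool`
#'   (per-metabolite pool concentration) and `totals` (per-sample
#'   total labeled-metabolite concentration, the simulated LC-UV
#'   readout).
#' @export
simulate_truth <- function(metabolome, design, biological_sigma = 0.15,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- design$samples
  long <- CJ(sample_id = samples$sample_id, id = metabolome$metabolites$id,
             sorted = FALSE)
  long <- merge(long, samples[, .(sample_id, group_id)], by = "sample_id")
  long <- merge(long, metabolome$metabolites[, .(id, base_conc)], by = "id")
  long <- merge(long, metabolome$multipliers, by = c("id", "group_id"))
  setorder(long, sample_id, id)
  long[, conc := base_conc * multiplier *
         rlnorm(.N, 0, biological_sigma)]

  pool <- long[, .(pool_conc = mean(conc)), by = id]
  long <- merge(long, pool, by = "id")
  long[, true_ratio := conc / pool_conc]

  totals <- long[, .(total = sum(conc)), by = sample_id]

  structure(list(
    concentrations = long[, .(sample_id, id, conc, true_ratio)],
    pool = pool[],
    totals = totals[]
  ), class = "cil_truth")
}

#' Instrument noise model for simulated labeled runs
#'
#' @param mz_sd_ppm Gaussian m/z error per centroid, in ppm.
#' @param rt_sd Gaussian retention-time jitter per metabolite per run,
#'   in seconds (shared by both channels, so co-elution is preserved).
#' @param intensity_sigma Lognormal sigma of the per-channel amplitude
#'   error (the dominant contribution to ratio error).
#' @param scan_sigma Lognormal sigma of additional per-scan intensity
#'   jitter.
#' @param detection_threshold Centroids below this intensity (counts)
#'   are not emitted by the instrument.
#' @param extra_dropout_prob Probability that a metabolite is entirely
#'   suppressed (both channels) in a given run, emulating matrix
#'   effects; such losses are not recoverable by zero-filling.
#' @param include_natural_isotopes Emit M+1 satellites (+1.003355 Da)
#'   with abundance approximately carbon count x 1.1%, exercising the
#'   isotope-exclusion rule of the pairing step.
#' @param noise_peaks_per_scan Mean number of chemical-noise centroids
#'   per scan, drawn just above the detection threshold.
#' @param peak_fwhm Chromatographic peak full width at half maximum, s.
#' @param scan_interval Time between MS1 scans, s (1 Hz acquisition).
#' @return A list of class `cil_noise`.
#' @export
noise_model <- function(mz_sd_ppm = 3, rt_sd = 3, intensity_sigma = 0.1,
                        scan_sigma = 0.05, detection_threshold = 500,
                        extra_dropout_prob = 0.01,
                        include_natural_isotopes = TRUE,
                        noise_peaks_per_scan = 5,
                        peak_fwhm = 8, scan_interval = 1) {
  stopifnot(mz_sd_ppm >= 0, rt_sd >= 0, intensity_sigma >= 0,
            scan_sigma >= 0, detection_threshold >= 0,
            extra_dropout_prob >= 0, extra_dropout_prob <= 1,
            peak_fwhm > 0, scan_interval > 0)
  structure(list(mz_sd_ppm = mz_sd_ppm, rt_sd = rt_sd,
                 intensity_sigma = intensity_sigma, scan_sigma = scan_sigma,
                 detection_threshold = detection_threshold,
                 extra_dropout_prob = extra_dropout_prob,
                 include_natural_isotopes = include_natural_isotopes,
                 noise_peaks_per_scan = noise_peaks_per_scan,
                 peak_fwhm = peak_fwhm, scan_interval = scan_interval),
            class = "cil_noise")
}
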