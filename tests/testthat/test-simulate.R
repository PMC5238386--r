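# Ground-truth simulation: pooling, determinism, noise-free limits.

zero_noise <- function() {
  noise_model(mz_sd_ppm = 0, rt_sd = 0, intensity_sigma = 0,
              scan_sigma = 0, detection_threshold = 0,
              extra_dropout_prob = 0, include_natural_isotopes = FALSE,
              noise_peaks_per_scan = 0)
}

test_that("pool concentration is the exact mean over samples", {
  design <- build_design(small_arms(), rats_per_group = 3,
                         duplicates = 1, dropped_groups = list())
  met <- simulate_metabolome(design, 20, 2, seed = 1)
  truth <- simulate_truth(met, design, seed = 2)
  means <- truth$concentrations[, .(m = mean(conc)), by = id]
  pool <- truth$pool[means$id, on = "id"]
  expect_equal(pool$pool_conc, means$m, tolerance = 1e-12)
  # true ratios are positive and consistent with conc / pool
  expect_true(all(truth$concentrations$true_ratio > 0))
})

test_that("metabolome simulation plants the requested markers and is
           seed-reproducible", {
  design <- build_design(small_arms(), dropped_groups = list())
  m1 <- simulate_metabolome(design, 50, 7, seed = 99)
  m2 <- simulate_metabolome(design, 50, 7, seed = 99)
  expect_identical(m1, m2)
  expect_equal(
    sum(m1$metabolites$trajectory_class == "treatment_reversing"), 7)
  m0 <- simulate_metabolome(design, 50, 0, seed = 99)
  expect_equal(
    sum(m0$metabolites$trajectory_class == "treatment_reversing"), 0)
  expect_error(simulate_metabolome(design, 5, 6), "exceed")
  expect_error(simulate_metabolome(design, 5, 1, mass_range = c(2, 2)),
               "empty mass range")
})

test_that("treatment-reversing multipliers rise then revert to sham", {
  design <- build_design(small_arms(), dropped_groups = list())
  met <- simulate_metabolome(design, 30, 3, seed = 5)
  planted <- met$metabolites[trajectory_class == "treatment_reversing",
                             id]
  mm <- merge(met$multipliers[id %in% planted],
              design$groups[, .(group_id, arm, week)], by = "group_id")
  oa <- mm[arm == "OA"][order(id, week)]
  # monotone non-decreasing over weeks 0-6 in the disease arm
  for (pid in planted) {
    v <- oa[id == pid & week <= 6, multiplier]
    expect_true(all(diff(v) >= 0))
  }
  # treated arms end at the sham level (multiplier 1) by week 14
  expect_equal(mm[arm %in% c("A", "B") & week == 14, multiplier],
               rep(1, 2 * length(planted)), tolerance = 1e-12)
  expect_equal(mm[arm == "sham", unique(multiplier)], 1)
})

test_that("zero-noise run reproduces exact masses, spacings and ratios", {
  design <- build_design(list(list(name = "g", operated = FALSE,
                                   treatment = "none", weeks = 0)),
                         rats_per_group = 2, duplicates = 1,
                         dropped_groups = list())
  # pin a single serine-like metabolite at an exact mass and RT
  met <- simulate_metabolome(design, 1, 0, mass_range = c(100, 110),
                             rt_range = c(290, 310),
                             tag_probs = c(1, 0, 0), seed = 3)
  met$metabolites[, `:=`(neutral_mass = 105.042593, rt = 300)]
  truth <- simulate_truth(met, design, biological_sigma = 0, seed = 4)
  # force the injected sample to twice the pool concentration
  truth$concentrations[, conc := 2 * truth$pool$pool_conc]
  sid <- truth$concentrations$sample_id[1]
  run <- simulate_run(sid, truth, met, zero_noise(), seed = 5)
  pairs <- detect_pairs(run, pair_params(sn_threshold = 1e-9))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$pair_mz, 339.10092, tolerance = 1e-4)
  expect_equal(pairs$n_tags, 1L)
  # exact heavy-light spacing and exact 2x ratio, noise-free
  feats <- extract_features(run, pair_params(sn_threshold = 1e-9))
  d <- diff(sort(unique(round(feats$features$mz, 5))))
  expect_equal(d[1], 2.00671, tolerance = 1e-5)
  expect_equal(pairs$chrom_ratio, 2, tolerance = 1e-9)
  expect_equal(pairs$ms_ratio, 2, tolerance = 1e-9)
})

test_that("QC runs mix pool against pool with unit true ratio", {
  study <- small_study()
  qc_runs <- runs_for(study$design$manifest, NULL, role = "qc")
  med <- median(ratio_matrix(study$table, qc_runs), na.rm = TRUE)
  expect_gt(med, 0.9)
  expect_lt(med, 1.1)
})

test_that("simulated runs are reproducible and reject unknown samples", {
  design <- build_design(small_arms(), rats_per_group = 2,
                         duplicates = 1, dropped_groups = list())
  met <- simulate_metabolome(design, 10, 1, seed = 7)
  truth <- simulate_truth(met, design, seed = 8)
  sid <- design$samples$sample_id[1]
  r1 <- simulate_run(sid, truth, met, seed = 11)
  r2 <- simulate_run(sid, truth, met, seed = 11)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_error(simulate_run("nope", truth, met, seed = 1),
               "unknown sample id")
})

test_that("runs round-trip through centroid CSV and mzML", {
  design <- build_design(small_arms(), rats_per_group = 2,
                         duplicates = 1, dropped_groups = list())
  met <- simulate_metabolome(design, 8, 0, seed = 21)
  truth <- simulate_truth(met, design, seed = 22)
  run <- simulate_run(design$samples$sample_id[1], truth, met, seed = 23)

  csv <- tempfile(fileext = ".csv")
  write_run_csv(run, csv)
  back <- read_run(csv)
  expect_equal(back$mz, run$mz, tolerance = 1e-12)
  expect_equal(back$rt, run$rt)
  expect_equal(back$intensity, run$intensity, tolerance = 1e-12)

  mzml <- tempfile(fileext = ".mzML")
  write_run_mzml(run, mzml)
  back2 <- read_run(mzml)
  expect_equal(nrow(back2), nrow(run))
  expect_equal(back2$mz, run$mz, tolerance = 1e-9)
  expect_equal(back2$intensity, run$intensity, tolerance = 1e-4)
})
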