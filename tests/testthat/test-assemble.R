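# Normalization, alignment, zero-filling, presence filtering.

test_that("LC-UV normalization: inverse volumes, unit mean factor,
           50-150% flags", {
  rec <- lcuv_normalize(c(a = 2, b = 1))
  expect_equal(rec$volume, c(1, 2))
  expect_equal(mean(rec$factor), 1)
  rec2 <- lcuv_normalize(c(x = 1, y = 1, z = 1))
  expect_equal(rec2$factor, rep(1, 3))
  expect_false(any(rec2$flag))
  tot <- c(rep(1, 9), 1.6 * (9 + 1.6) / 10)  # last near 1.6 x mean
  tot <- c(rep(1, 9), 2)                      # factor 2/1.1 > 1.5
  rec3 <- lcuv_normalize(tot)
  expect_equal(which(rec3$flag), 10L)
  expect_error(lcuv_normalize(c(1, -1)), "positive")
})

fake_pairs <- function(mz, rt, ratio = 1, intensity = 1e6, n_tags = 1) {
  data.table(light = seq_along(mz), heavy = seq_along(mz) + 100,
             n_tags = n_tags, pair_mz = mz, rt = rt,
             delta_ppm = 0, intensity = intensity,
             ms_ratio = ratio, chrom_ratio = ratio)
}

test_that("alignment merges within tolerance and splits beyond it", {
  p1 <- fake_pairs(400, 150)
  p2 <- fake_pairs(400 * (1 + 5e-6), 152)
  tab <- align_runs(list(r1 = p1, r2 = p2))
  expect_equal(nrow(tab$rows), 1)
  expect_equal(sum(tab$provenance == "detected"), 2)

  p3 <- fake_pairs(400 * (1 + 25e-6), 152)
  tab2 <- align_runs(list(r1 = p1, r2 = p3))
  expect_equal(nrow(tab2$rows), 2)
})

test_that("alignment conserves pairs and never doubles a run in a row", {
  study <- small_study()
  tab <- align_runs(study$pair_tables,
                    manifest = study$design$manifest)
  n_in <- sum(vapply(study$pair_tables, nrow, integer(1)))
  expect_equal(sum(tab$provenance == "detected"), n_in)
  # every aligned run appears at most once per row by construction
  expect_true(all(table(tab$rows$row_id) == 1))
  # consensus equals intensity-weighted means of members: spot-check
  # against a one-row rebuild
  expect_equal(nrow(tab$rows),
               nrow(study$table$rows))  # presence filter kept all
})

test_that("default simulation aligns to about one row per metabolite", {
  study <- small_study()
  expect_equal(nrow(study$table$rows),
               nrow(study$metabolome$metabolites))
})

test_that("zero-filling is monotone and never overwrites detections", {
  study <- small_study()
  tab0 <- align_runs(study$pair_tables,
                     manifest = study$design$manifest)
  tab1 <- zero_fill(tab0, study$runs)
  det0 <- tab0$provenance == "detected"
  expect_true(all(tab1$provenance[det0] == "detected"))
  expect_equal(tab1$ratios[det0], tab0$ratios[det0])
  expect_gte(sum(tab1$provenance != "missing"),
             sum(tab0$provenance != "missing"))
  filled <- tab1$provenance == "zero_filled"
  expect_true(all(tab1$ratios[filled] > 0))
})

test_that("zero-filling recovers a pair sitting just under the picking
           threshold", {
  cc <- chem_constants()
  set.seed(61)
  # singleton chemical-noise centroids ground the noise estimate at
  # ~100 counts, so the picker demands ~300 and the relaxed
  # zero-fill re-search ~100
  noise_cent <- function() data.table(rt = seq(1, 200),
                                      mz = runif(200, 300, 900),
                                      intensity = 100)
  strong <- make_run(gauss_trace(400.2, 100, 1e5),
                     gauss_trace(400.2 + cc$tag_delta, 100, 5e4),
                     noise_cent(), run_id = "strong")
  weak <- make_run(gauss_trace(400.2, 100, 150),
                   gauss_trace(400.2 + cc$tag_delta, 100, 290),
                   noise_cent(), run_id = "weak")
  p_strong <- detect_pairs(strong)
  p_weak <- detect_pairs(weak)
  expect_equal(nrow(p_strong), 1)
  expect_equal(nrow(p_weak), 0)  # below 3x noise, not picked
  tab <- align_runs(list(strong = p_strong, weak = p_weak))
  expect_equal(unname(tab$provenance[1, "weak"]), "missing")
  tab <- zero_fill(tab, list(strong = strong, weak = weak))
  expect_equal(unname(tab$provenance[1, "weak"]), "zero_filled")
  # the filled ratio reflects the true 150/290 amplitude ratio within
  # the workflow's 20% accuracy bound (thresholding near the noise
  # floor truncates the weaker channel more, biasing the ratio low)
  expect_lt(abs(unname(tab$ratios[1, "weak"]) / (150 / 290) - 1), 0.2)
})

test_that("zero-filling a second time changes nothing", {
  study <- small_study()
  tab1 <- study$table
  tab2 <- zero_fill(tab1, study$runs)
  expect_equal(tab2$ratios, tab1$ratios)
  expect_equal(tab2$provenance, tab1$provenance)
})

test_that("cells of metabolites truly absent from a run stay missing", {
  # a pair planted in run 1 only; run 2 contains unrelated signal
  p1 <- rbind(fake_pairs(400, 150), fake_pairs(520, 300))
  p2 <- fake_pairs(520, 300)
  r2 <- make_run(gauss_trace(520, 300, 1e5),
                 gauss_trace(520 + chem_constants()$tag_delta, 300,
                             1e5),
                 run_id = "r2")
  r1 <- make_run(gauss_trace(400, 150, 1e5),
                 gauss_trace(400 + chem_constants()$tag_delta, 150,
                             1e5),
                 gauss_trace(520, 300, 1e5),
                 gauss_trace(520 + chem_constants()$tag_delta, 300,
                             1e5),
                 run_id = "r1")
  tab <- align_runs(list(r1 = p1, r2 = p2))
  tab <- zero_fill(tab, list(r1 = r1, r2 = r2))
  i400 <- which.min(abs(tab$rows$mz - 400))
  expect_equal(unname(tab$provenance[i400, "r2"]), "missing")
})

test_that("presence filter uses a strict inequality and is idempotent", {
  prov <- matrix("missing", 2, 6,
                 dimnames = list(c("row0001", "row0002"),
                                 paste0("r", 1:6)))
  prov[1, 1:3] <- "detected"            # 3 of 6 -> dropped
  prov[2, 1:3] <- "detected"
  prov[2, 4] <- "zero_filled"           # 4 of 6 -> kept
  ratios <- matrix(1, 2, 6, dimnames = dimnames(prov))
  ratios[prov == "missing"] <- NA
  tab <- structure(list(
    rows = data.table(row_id = rownames(prov), mz = c(400, 500),
                      rt = c(100, 200), n_tags = c(1L, 1L)),
    ratios = ratios, provenance = prov,
    runs = data.table(run_id = colnames(prov), role = "sample")),
    class = "cil_table")
  f1 <- presence_filter(tab, 0.5)
  expect_equal(f1$rows$row_id, "row0002")
  f2 <- presence_filter(f1, 0.5)
  expect_equal(f2$rows, f1$rows)
  expect_equal(f2$ratios, f1$ratios)
  # zero-filled cells can be discounted
  f3 <- presence_filter(tab, 0.5, count_zero_filled = FALSE)
  expect_equal(nrow(f3$rows), 0)
})
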