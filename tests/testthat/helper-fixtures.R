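# Shared fixtures and independent oracles for the test suite.

library(data.table)

# ---- synthetic runs built directly from Gaussian traces ------------

# One Gaussian chromatographic trace as centroids on a 1 s grid.
gauss_trace <- function(mz, rt_apex, height, fwhm = 8,
                        rt_range = c(rt_apex - 20, rt_apex + 20)) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- seq(ceiling(rt_range[1]), floor(rt_range[2]))
  data.table(rt = t, mz = mz,
             intensity = height * exp(-(t - rt_apex)^2 / (2 * sigma^2)))
}

# Assemble traces into a cil_run-like centroid table.
make_run <- function(..., run_id = "test") {
  cent <- rbindlist(list(...))
  setorder(cent, rt, mz)
  cilquant:::.as_cil_run(cent, run_id, run_id, 1)
}

# ---- brute-force pairing oracle ------------------------------------

# Exhaustive all-pairs search applying the documented predicates and
# the same greedy assignment, independent of the package's indexed
# implementation.
brute_force_pairs <- function(features, params = pair_params()) {
  ft <- as.data.table(features)
  setorder(ft, mz)
  cc <- chem_constants()
  n <- nrow(ft)
  if (n < 2) return(data.table(light = integer(0), heavy = integer(0),
                               n_tags = integer(0)))
  # isotope exclusion per light candidate
  excl <- sapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i &&
        abs(ft$mz[i] - params$isotope_delta - ft$mz[j]) <=
          params$mz_tol_ppm * 1e-6 * ft$mz[i] &&
        abs(ft$rt[j] - ft$rt[i]) <= params$rt_coelution_tol &&
        ft$height[j] > ft$height[i]
    }, logical(1)))
  })
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || excl[i]) next
      for (k in params$n_tags_range) {
        if (abs(ft$mz[j] - ft$mz[i] - k * cc$tag_delta) <=
              params$mz_tol_ppm * 1e-6 * ft$mz[i] &&
            abs(ft$rt[j] - ft$rt[i]) <= params$rt_coelution_tol) {
          cand[[length(cand) + 1]] <- data.table(
            light = i, heavy = j, n_tags = k,
            intensity = ft$area[i] + ft$area[j], pair_mz = ft$mz[i])
        }
      }
    }
  }
  if (!length(cand)) return(data.table(light = integer(0),
                                       heavy = integer(0),
                                       n_tags = integer(0)))
  cand <- rbindlist(cand)
  setorder(cand, -intensity, pair_mz, n_tags)
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used[cand$light[r]] && !used[cand$heavy[r]]) {
      used[cand$light[r]] <- used[cand$heavy[r]] <- TRUE
      keep[r] <- TRUE
    }
  }
  out <- cand[keep]
  out[, light := ft$feature[light]]
  out[, heavy := ft$feature[heavy]]
  setorder(out, light)
  out[, .(light, heavy, n_tags)]
}

# random feature tables for the oracle-equivalence property
random_features <- function(n, seed) {
  set.seed(seed)
  cc <- chem_constants()
  base_mz <- runif(n, 300, 900)
  # make a fraction of features deliberate heavy partners / isotopes
  shift <- sample(c(0, cc$tag_delta, 2 * cc$tag_delta,
                    cc$c13_c12_spacing),
                  n, replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.2))
  partner <- sample(n, n, replace = TRUE)
  mz <- ifelse(shift > 0, base_mz[partner] + shift +
                 rnorm(n, 0, 1e-3), base_mz)
  data.table(feature = seq_len(n), mz = mz,
             rt = sample(seq(100, 200, by = 5), n, replace = TRUE) +
               rnorm(n, 0, 2),
             height = rlnorm(n, 10, 1))[, area := height * 8][]
}

# ---- small simulated study, built once and cached ------------------

.fixture_cache <- new.env(parent = emptyenv())

small_arms <- function() {
  list(
    list(name = "sham", operated = TRUE, treatment = "none",
         weeks = c(0, 2, 4, 6, 14)),
    list(name = "OA", operated = TRUE, treatment = "none",
         weeks = c(0, 2, 4, 6, 14)),
    list(name = "A", operated = TRUE, treatment = "A", weeks = c(8, 14)),
    list(name = "B", operated = TRUE, treatment = "B", weeks = c(8, 14))
  )
}

# A compact study exercising every pipeline stage: 2 control/disease
# arms, 2 treatment arms, 4 rats, duplicate injections, 60
# metabolites with 4 planted markers.
small_study <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  design <- build_design(small_arms(), rats_per_group = 4,
                         duplicates = 2, qc_interval = 10,
                         dropped_groups = list())
  metabolome <- simulate_metabolome(design, n_metabolites = 60,
                                    n_biomarkers = 4, seed = 421)
  truth <- simulate_truth(metabolome, design, seed = 422)
  runs <- simulate_study(design, truth, metabolome, seed = 423)
  pair_tables <- lapply(runs, detect_pairs)
  table <- align_runs(pair_tables, manifest = design$manifest)
  table <- zero_fill(table, runs)
  table <- presence_filter(table)
  .fixture_cache$small <- list(design = design, metabolome = metabolome,
                               truth = truth, runs = runs,
                               pair_tables = pair_tables, table = table)
  .fixture_cache$small
}

# row ids of the planted markers in the small study's table
planted_rows <- function(study) {
  planted <- study$metabolome$metabolites[
    trajectory_class == "treatment_reversing"]
  pmz <- labeled_mz(planted$neutral_mass, planted$n_tags, "light")
  study$table$rows[
    sapply(mz, function(z) any(abs(z - pmz) < 0.01)), row_id]
}
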