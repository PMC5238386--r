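# Configuration and end-to-end orchestration.

.default_config <- function() {
  list(
    seed = 1,
    # study design
    rats_per_group = 6, duplicates = 2, qc_interval = 10,
    # simulation
    n_metabolites = 300, n_biomarkers = 11, biological_sigma = 0.15,
    use_library_compounds = TRUE,
    # detection / alignment
    mz_tol_ppm = 10, rt_coelution_tol = 10, sn_threshold = 3,
    min_scans = 4, align_rt_tol = 20,
    # zero-filling and presence
    zero_fill_rt_window = 15, zero_fill_relaxed_sn = 1,
    presence_fraction = 0.5,
    # statistics
    fc_threshold = 1.2, alpha = 0.05,
    # marker selection
    disease_arm = "OA", control_arm = "sham",
    disease_weeks = c(2, 4, 6), trend_weeks = c(0, 2, 4, 6),
    treat_weeks = c(8, 14), allow_missing = 1,
    # stages
    do_stats = TRUE, do_annotation = TRUE,
    # output
    out_dir = NULL
  )
}

#' Pipeline configuration
#'
#' Returns the default configuration -- whose tolerances reproduce
#' the workflow's standard parameter set (10 ppm mass tolerance, 60 s
#' library RT tolerance, QC every 10 runs, presence > 50%, 1.2-fold
#' / p <= 0.05 significance) -- overridden by any named arguments.
#' Unknown keys fail fast.
#'
#' @param ... Named overrides of default keys.
#' @return A named list of class `cil_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("invalid config key(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  structure(cfg, class = "cil_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_config`, a `cil_config`; unknown keys in the
#'   file fail fast.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `cil_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full CIL LC-MS pipeline on a simulated study
#'
#' Simulates the configured study (design, ground-truth metabolome,
#' labeled runs), detects and quantifies peak pairs per run, aligns
#' them into the ratio table, zero-fills missing cells from the raw
#' centroids, applies the presence filter, computes LC-UV
#' normalization records, annotates the surviving rows, fits PCA and
#' OPLS-DA models of the disease contrast, runs the volcano
#' comparisons, and selects biomarker candidates.  All randomness
#' derives from `config$seed`, so identical configurations give
#' identical results.
#'
#' @param config A [pipeline_config()].
#' @param runs Optional pre-simulated named list of `cil_run`s (with
#'   `design`, `truth`, `metabolome` attributes set by the caller);
#'   normally NULL and everything is simulated from the config.
#' @param quiet Suppress progress messages.
#' @return A `cil_pipeline` list: `design`, `metabolome`, `truth`,
#'   `table` (filtered ratio table), `normalization`, `annotation`,
#'   `stats` (PCA/OPLS-DA), `markers`, `log` (per-run feature and
#'   pair counts) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "cil_config"))
  say <- function(...) if (!quiet) message(...)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 4)

  say("building design ...")
  design <- build_design(rats_per_group = config$rats_per_group,
                         duplicates = config$duplicates,
                         qc_interval = config$qc_interval)
  metabolome <- simulate_metabolome(
    design, n_metabolites = config$n_metabolites,
    n_biomarkers = config$n_biomarkers,
    library_compounds = if (isTRUE(config$use_library_compounds)) {
      load_dansyl_library()
    },
    seed = seeds[1])
  truth <- simulate_truth(metabolome, design,
                          biological_sigma = config$biological_sigma,
                          seed = seeds[2])
  say("simulating ", nrow(design$manifest), " runs ...")
  runs <- simulate_study(design, truth, metabolome, seed = seeds[3])

  params <- pair_params(mz_tol_ppm = config$mz_tol_ppm,
                        rt_coelution_tol = config$rt_coelution_tol,
                        sn_threshold = config$sn_threshold,
                        min_scans = config$min_scans)
  say("detecting peak pairs ...")
  pair_tables <- lapply(runs, detect_pairs, params = params)
  log <- data.table(
    run_id = names(runs),
    n_centroids = vapply(runs, nrow, integer(1)),
    n_pairs = vapply(pair_tables, nrow, integer(1))
  )
  say(sprintf("pairs per run: %.0f +/- %.0f",
              mean(log$n_pairs), sd(log$n_pairs)))

  say("aligning ...")
  table <- align_runs(pair_tables, mz_tol_ppm = config$mz_tol_ppm,
                      rt_tol = config$align_rt_tol,
                      manifest = design$manifest)
  say("zero-filling ...")
  table <- zero_fill(table, runs, params,
                     rt_window = config$zero_fill_rt_window,
                     relaxed_sn = config$zero_fill_relaxed_sn)
  log[, n_zero_filled := colSums(table$provenance == "zero_filled")]
  table <- presence_filter(table, config$presence_fraction)
  say("ratio table: ", nrow(table$rows), " aligned pairs kept")

  normalization <- lcuv_normalize(truth$totals)

  annotation <- if (config$do_annotation) annotate_table(table) else NULL

  stats <- NULL
  if (config$do_stats) {
    say("fitting latent-variable models ...")
    dz_runs <- unlist(lapply(c(0, config$disease_weeks), function(w) {
      c(runs_for(design$manifest, config$disease_arm, w),
        runs_for(design$manifest, config$control_arm, w))
    }))
    dz_runs <- intersect(design$manifest$run_id, dz_runs)
    labels <- design$manifest[match(dz_runs, run_id), arm]
    stats <- list(
      pca = cil_pca(preprocess_matrix(table, runs = dz_runs), k = 2),
      oplsda = cil_oplsda(preprocess_matrix(table, runs = dz_runs),
                          labels == config$disease_arm)
    )
  }

  say("selecting markers ...")
  markers <- select_markers(
    table, disease_arm = config$disease_arm,
    control_arm = config$control_arm,
    disease_weeks = config$disease_weeks,
    trend_weeks = config$trend_weeks,
    treat_weeks = config$treat_weeks,
    fc_threshold = config$fc_threshold, alpha = config$alpha,
    allow_missing = config$allow_missing)
  say(nrow(markers$markers), " marker candidate(s)")

  out <- structure(list(design = design, metabolome = metabolome,
                        truth = truth, table = table,
                        normalization = normalization,
                        annotation = annotation, stats = stats,
                        markers = markers, log = log, config = config),
                   class = "cil_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

#' Write the result bundle of a pipeline run to disk
#'
#' CSV tables plus a JSON manifest of parameters and seed.
#'
#' @param result A `cil_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest_csv(result$design, file.path(dir, "manifest.csv"))
  write_truth_csv(result$truth, file.path(dir, "truth.csv"))
  fwrite(result$table$rows, file.path(dir, "table_rows.csv"))
  rr <- as.data.table(result$table$ratios, keep.rownames = "row_id")
  fwrite(rr, file.path(dir, "table_ratios.csv"))
  pp <- as.data.table(result$table$provenance, keep.rownames = "row_id")
  fwrite(pp, file.path(dir, "table_provenance.csv"))
  fwrite(result$normalization, file.path(dir, "normalization.csv"))
  if (!is.null(result$annotation)) {
    fwrite(result$annotation, file.path(dir, "annotation.csv"))
  }
  fwrite(result$markers$markers, file.path(dir, "markers.csv"))
  fwrite(result$log, file.path(dir, "run_log.csv"))
  meta <- list(package = "cilquant",
               version = as.character(utils::packageVersion("cilquant")),
               config = unclass(result$config))
  jsonlite::write_json(meta, file.path(dir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
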