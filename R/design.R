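# Study design: arms, weeks, replicates, injection schedule.

#' Default arms of the rat osteoarthritis study design
#'
#' Three longitudinal arms (un-operated normal controls, sham-operated
#' controls, and surgically induced OA) sampled biweekly from week 0
#' to week 14, plus four treatment arms (drugs A-D, administered to OA
#' rats from week 6) sampled biweekly from week 8 to week 14.
#'
#' @return A list of arm definitions, each a list with `name`,
#'   `operated`, `treatment` and `weeks`.
#' @export
oa_study_arms <- function() {
  full <- seq(0, 14, by = 2)
  late <- seq(8, 14, by = 2)
  list(
    list(name = "normal", operated = FALSE, treatment = "none", weeks = full),
    list(name = "sham",   operated = TRUE,  treatment = "none", weeks = full),
    list(name = "OA",     operated = TRUE,  treatment = "none", weeks = full),
    list(name = "A", operated = TRUE, treatment = "A", weeks = late),
    list(name = "B", operated = TRUE, treatment = "B", weeks = late),
    list(name = "C", operated = TRUE, treatment = "C", weeks = late),
    list(name = "D", operated = TRUE, treatment = "D", weeks = late)
  )
}

#' Build a longitudinal study design with sample and run manifests
#'
#' Enumerates every (arm, week) group, assigns `rats_per_group`
#' animals per group and `duplicates` injections per animal, and
#' interleaves pooled-sample QC injections every `qc_interval` sample
#' runs.  The default arguments reproduce the rat OA design: 39
#' groups, 234 samples, 468 duplicate runs and 46 QC injections (the
#' sham week-12 group is dropped, mirroring the misplaced samples of
#' that study).
#'
#' @param arms List of arm definitions as returned by
#'   [oa_study_arms()].
#' @param rats_per_group Animals per (arm, week) group.
#' @param duplicates LC-MS injections per sample.
#' @param qc_interval A QC injection follows each completed block of
#'   this many sample runs.
#' @param dropped_groups List of `list(arm=, week=)` groups to remove
#'   from the enumeration (they must exist in it).
#' @return An object of class `cil_design`: a list with `groups`,
#'   `samples` and `manifest` data.tables.  The manifest has one row
#'   per injection with columns `run_id`, `sample_id`, `arm`, `week`,
#'   `rat_index`, `duplicate_index`, `role` and `treatment`.
#' @export
build_design <- function(arms = oa_study_arms(), rats_per_group = 6,
                         duplicates = 2, qc_interval = 10,
                         dropped_groups = list(list(arm = "sham", week = 12))) {
  if (rats_per_group < 1) stop("rats_per_group must be >= 1")
  if (duplicates < 1) stop("duplicates must be >= 1")

  groups <- rbindlist(lapply(arms, function(a) {
    data.table(arm = a$name, week = as.integer(a$weeks),
               operated = a$operated, treatment = a$treatment)
  }))
  if (anyDuplicated(groups[, .(arm, week)])) {
    stop("duplicate group definitions in arms")
  }
  for (dg in dropped_groups) {
    hit <- groups$arm == dg$arm & groups$week == dg$week
    if (!any(hit)) {
      stop("dropped group not in enumeration: ", dg$arm, " week ", dg$week)
    }
    groups <- groups[!hit]
  }
  setorder(groups, arm, week)
  groups[, group_id := sprintf("%s_w%02d", arm, week)]

  samples <- groups[rep(seq_len(.N), each = rats_per_group)]
  samples[, rat_index := rep(seq_len(rats_per_group), times = nrow(groups))]
  samples[, sample_id := sprintf("%s_r%d", group_id, rat_index)]

  sruns <- samples[rep(seq_len(.N), each = duplicates)]
  sruns[, duplicate_index := rep(seq_len(duplicates), times = nrow(samples))]
  sruns[, role := "sample"]

  sched <- schedule_runs(nrow(sruns), qc_interval)
  manifest <- sched[, {
    if (role == "sample") {
      sruns[sample_index, .(sample_id, arm, week, rat_index,
                            duplicate_index, role = "sample",
                            treatment, group_id)]
    } else {
      data.table(sample_id = "QC", arm = "QC", week = NA_integer_,
                 rat_index = NA_integer_, duplicate_index = qc_index,
                 role = "qc", treatment = "none", group_id = "QC")
    }
  }, by = .(slot, sample_index, qc_index)][, -c("sample_index", "qc_index")]
  manifest[, run_id := sprintf("run%04d", slot)]
  setcolorder(manifest, c("run_id", "sample_id", "arm", "week", "rat_index",
                          "duplicate_index", "role", "treatment", "group_id",
                          "slot"))

  structure(list(groups = groups[], samples = samples[],
                 manifest = manifest[],
                 rats_per_group = rats_per_group, duplicates = duplicates,
                 qc_interval = qc_interval),
            class = "cil_design")
}

#' @export
print.cil_design <- function(x, ...) {
  cat("CIL study design:", nrow(x$groups), "groups,",
      nrow(x$samples), "samples,",
      sum(x$manifest$role == "sample"), "sample runs,",
      sum(x$manifest$role == "qc"), "QC injections\n")
  invisible(x)
}

#' Injection schedule with interleaved QC runs
#'
#' One pooled-sample QC injection is appended after each completed
#' block of `qc_interval` sample runs, so the number of QC injections
#' is `floor(n_sample_runs / qc_interval)`.
#'
#' @param n_sample_runs Number of sample injections (>= 0).
#' @param qc_interval Sample runs per QC block (>= 1).
#' @return A data.table with columns `slot` (acquisition order),
#'   `role` (`"sample"` or `"qc"`), `sample_index` (index into the
#'   sample-run sequence, NA for QC) and `qc_index`.
#' @export
schedule_runs <- function(n_sample_runs, qc_interval) {
  if (qc_interval < 1) stop("qc_interval must be >= 1")
  if (n_sample_runs < 0) stop("n_sample_runs must be >= 0")
  n_qc <- n_sample_runs %/% qc_interval
  role <- character(0)
  sample_index <- integer(0)
  qc_index <- integer(0)
  si <- 0L
  qi <- 0L
  while (si < n_sample_runs) {
    take <- min(qc_interval, n_sample_runs - si)
    role <- c(role, rep("sample", take))
    sample_index <- c(sample_index, si + seq_len(take))
    qc_index <- c(qc_index, rep(NA_integer_, take))
    si <- si + take
    if (take == qc_interval) {
      qi <- qi + 1L
      role <- c(role, "qc")
      sample_index <- c(sample_index, NA_integer_)
      qc_index <- c(qc_index, qi)
    }
  }
  stopifnot(qi == n_qc)
  data.table(slot = seq_along(role), role = role,
             sample_index = sample_index, qc_index = qc_index)
}
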