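# Time-course biomarker selection: per-week significant sets,
# cross-time intersection with one-missing tolerance, trend
# filtering, and disease-marker x treatment-response cross-reference.

#' Significant rows of a volcano comparison as a direction-signed set
#'
#' @param volcano Output of [volcano_compare()].
#' @return A data.table `row_id`, `direction`, `fold_change` of the
#'   significant rows.
#' @export
significant_set <- function(volcano) {
  volcano[significant %in% TRUE,
          .(row_id, direction, fold_change)]
}

#' Rows significant across time points, tolerating a few misses
#'
#' A row is retained when it appears in at least
#' `length(sets) - allow_missing` of the per-time-point significant
#' sets and its direction of change agrees in every set where it
#' appears.
#'
#' @param sets List of significant sets (see [significant_set()]).
#' @param allow_missing Number of sets a row may be absent from
#'   (must be `< length(sets)`).
#' @return A data.table `row_id`, `direction`, `n_sets`.
#' @export
common_across_time <- function(sets, allow_missing = 1) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (allow_missing >= length(sets)) {
    stop("allow_missing must be smaller than the number of sets")
  }
  all <- rbindlist(lapply(sets, function(s) {
    as.data.table(s)[, .(row_id, direction)]
  }))
  agg <- all[, .(n_sets = .N, consistent = uniqueN(direction) == 1,
                 direction = direction[1]), by = row_id]
  agg[n_sets >= length(sets) - allow_missing & consistent,
      .(row_id, direction, n_sets)]
}

#' Per-group trend profiles of aligned pairs
#'
#' Mean and SD of the observed ratios of each row in each (arm,
#' week) group, optionally expressed relative to a reference arm at
#' the same week (ratio of group means).
#'
#' @param table A `cil_table` with manifest metadata in `runs`.
#' @param arm Arm whose trajectory is profiled.
#' @param weeks Weeks to include, ascending.
#' @param ref_arm Optional reference arm; when given, `mean` is the
#'   arm/reference ratio of group means.
#' @return A data.table `row_id`, `week`, `mean`, `sd`, `n`.
#' @export
trend_profiles <- function(table, arm, weeks, ref_arm = NULL) {
  manifest <- table$runs
  rbindlist(lapply(sort(weeks), function(w) {
    ra <- runs_for(manifest, arm, w)
    m <- ratio_matrix(table, ra)
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1, sd, na.rm = TRUE)
    n <- rowSums(!is.na(m))
    if (!is.null(ref_arm)) {
      rb <- runs_for(manifest, ref_arm, w)
      mu <- mu / rowMeans(ratio_matrix(table, rb), na.rm = TRUE)
    }
    data.table(row_id = table$rows$row_id, week = w, mean = mu,
               sd = sdv, n = n)
  }))
}

#' Filter rows whose group-mean trajectory changes gradually
#'
#' Formalizes "levels changed gradually over time" as tolerant
#' monotonicity on the log scale: the net change across the profiled
#' weeks must reach `min_fold`, and no adjacent step may oppose the
#' net direction by more than `backtrack` times the magnitude of the
#' net change.
#'
#' @param profiles Output of [trend_profiles()], spanning at least 3
#'   weeks.
#' @param min_fold Minimum net fold change.  The default asks for a
#'   little more than the volcano threshold because a net change is
#'   measured on noisy group means: at six animals per group the
#'   standard error of a group-mean ratio is close to 10%, and a
#'   1.2-fold net requirement alone would pass a fifth of purely
#'   drifting metabolites.
#' @param backtrack Allowed opposing step, as a fraction of the net
#'   log change.  Opposing steps of a truly monotone trajectory are
#'   sampling noise, so the tolerance is generous; the net-change
#'   requirement carries the selectivity.
#' @return A data.table `row_id`, `direction`, `net_fold`.
#' @export
trend_filter <- function(profiles, min_fold = 1.3, backtrack = 0.75) {
  prof <- as.data.table(profiles)
  if (nrow(prof) == 0) {
    return(data.table(row_id = character(0), direction = numeric(0),
                      net_fold = numeric(0)))
  }
  if (uniqueN(prof$week) < 3) stop("profiles must span >= 3 weeks")
  setorder(prof, row_id, week)
  res <- prof[, {
    m <- log(mean)
    ok <- all(is.finite(m))
    if (ok) {
      net <- m[length(m)] - m[1]
      steps <- diff(m)
      ok <- abs(net) >= log(min_fold) &&
        all(sign(net) * steps >= -backtrack * abs(net))
    }
    .(pass = ok,
      direction = if (ok) sign(m[length(m)] - m[1]) else NA_real_,
      net_fold = if (ok) exp(abs(m[length(m)] - m[1])) else NA_real_)
  }, by = row_id]
  res[pass == TRUE, .(row_id, direction, net_fold)]
}

#' Cross-reference disease markers with treatment-response markers
#'
#' Intersects the two candidate sets (requiring agreeing directions
#' when both carry one) and ranks the result by completeness -- the
#' fraction of runs, and of samples (a sample counts when any of its
#' duplicate runs observed the row), in which the pair was observed
#' -- then by fold-change magnitude.
#'
#' @param oa_markers,curing_markers data.tables with `row_id` (and
#'   optionally `direction`, `net_fold`) from the same `cil_table`.
#' @param table That `cil_table`.
#' @param completeness_min Minimum run-level completeness.
#' @return A data.table `row_id`, `direction`, `net_fold`,
#'   `completeness_runs`, `completeness_samples`.
#' @export
cross_reference <- function(oa_markers, curing_markers, table,
                            completeness_min = 0) {
  oa <- as.data.table(oa_markers)
  cu <- as.data.table(curing_markers)
  common <- intersect(oa$row_id, cu$row_id)
  if ("direction" %in% names(oa) && "direction" %in% names(cu)) {
    da <- oa[match(common, row_id), direction]
    db <- cu[match(common, row_id), direction]
    common <- common[is.na(da) | is.na(db) | da == db]
  }
  if (!length(common)) {
    return(data.table(row_id = character(0), direction = numeric(0),
                      net_fold = numeric(0),
                      completeness_runs = numeric(0),
                      completeness_samples = numeric(0)))
  }
  idx <- match(common, table$rows$row_id)
  obs <- table$provenance[idx, , drop = FALSE] != "missing"
  manifest <- table$runs
  scol <- if ("role" %in% names(manifest)) manifest$role == "sample" else
    rep(TRUE, ncol(obs))
  obs_s <- obs[, scol, drop = FALSE]
  comp_runs <- rowMeans(obs_s)
  sample_ids <- manifest$sample_id[scol]
  comp_samples <- apply(obs_s, 1, function(v) {
    mean(tapply(v, sample_ids, any))
  })
  out <- data.table(
    row_id = common,
    direction = if ("direction" %in% names(oa)) {
      oa[match(common, row_id), direction]
    } else NA_real_,
    net_fold = if ("net_fold" %in% names(oa)) {
      oa[match(common, row_id), net_fold]
    } else NA_real_,
    completeness_runs = comp_runs,
    completeness_samples = comp_samples
  )
  out <- out[completeness_runs >= completeness_min]
  setorder(out, -completeness_runs, -net_fold, na.last = TRUE)
  out[]
}

#' Exclusive-region counts of 2 to 4 sets (Venn counts)
#'
#' @param sets Named list of 2-4 vectors.
#' @return Named integer vector, one entry per exclusive membership
#'   region (names like `"A"`, `"A&B"`); entries sum to the size of
#'   the union.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_counts supports 2 to 4 sets")
  nm <- names(sets) %||% LETTERS[seq_len(k)]
  if (is.null(names(sets))) names(sets) <- nm
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  key <- apply(memb, 1, function(row) paste(nm[row], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(m) {
    combn(nm, m, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = regions))
  out <- as.integer(counts)
  names(out) <- regions
  out
}

#' End-to-end biomarker selection on a ratio table
#'
#' Implements the time-course selection logic of the labeled rat
#' study:
#'
#' 1. Volcano comparisons of the disease arm vs. its control at each
#'    disease week; rows significant in all but `allow_missing`
#'    weeks with consistent direction are disease candidates.
#' 2. The candidates' disease/control trajectories over
#'    `trend_weeks` must change gradually ([trend_filter()]) --
#'    these are the disease (OA) markers.
#' 3. Volcano comparisons of early vs. final treatment week within
#'    each treatment arm; rows significant in all but
#'    `allow_missing` arms (at most `n_arms - 1`) with consistent
#'    direction are treatment-response candidates.
#' 4. A candidate reverts when, in at least half of the treatment
#'    arms, the final-week treated group either shows no significant
#'    volcano difference from the control arm at that week (the
#'    fold-change prong doubles as a +/-20% band around the control
#'    level) or has moved at least `1 - reversion_band` of the
#'    final-week control-disease log gap away from the disease
#'    level, toward the control.  The relative clause mirrors how
#'    reversion is judged in practice -- "the large disease/control
#'    difference reduced to no difference" -- and, being anchored at
#'    the disease arm on both sides of the comparison, it is robust
#'    to a chance off draw of any single reference group, which
#'    would otherwise fail every treatment arm at once (all arms
#'    share the same control animals).  Candidates passing this are
#'    the curing markers.
#' 5. [cross_reference()] of disease and curing markers, ranked by
#'    completeness, gives the reported candidates.
#'
#' @param table A `cil_table` whose `runs` carry manifest metadata.
#' @param disease_arm,control_arm Arms compared during disease
#'   development.
#' @param disease_weeks Weeks of the disease-phase comparisons.
#' @param trend_weeks Weeks profiled by the trend filter.
#' @param treat_weeks Early and final treatment weeks compared
#'   within each treatment arm.
#' @param fc_threshold,alpha Volcano thresholds.
#' @param allow_missing One-missing tolerance for the cross-time and
#'   cross-treatment intersections.
#' @param backtrack Trend-filter backtrack tolerance.
#' @param reversion_band Fraction of the disease arm's final-week log
#'   gap that a treated group may retain and still count as
#'   reverted.
#' @param min_fold Trend-filter net fold change.
#' @return A `cil_markers` list: `markers` (final candidates),
#'   `oa_markers`, `curing_markers`, and the underlying volcano
#'   tables.
#' @export
select_markers <- function(table, disease_arm = "OA",
                           control_arm = "sham",
                           disease_weeks = c(2, 4, 6),
                           trend_weeks = c(0, 2, 4, 6),
                           treat_weeks = c(8, 14),
                           fc_threshold = 1.2, alpha = 0.05,
                           allow_missing = 1, backtrack = 0.75,
                           min_fold = 1.3, reversion_band = 0.5) {
  manifest <- table$runs
  stopifnot(all(c("arm", "week", "role") %in% names(manifest)))

  disease_volcano <- lapply(disease_weeks, function(w) {
    volcano_compare(table, runs_for(manifest, disease_arm, w),
                    runs_for(manifest, control_arm, w),
                    fc_threshold, alpha)
  })
  names(disease_volcano) <- paste0("week", disease_weeks)
  s1 <- common_across_time(lapply(disease_volcano, significant_set),
                           allow_missing)

  prof <- trend_profiles(table, disease_arm, trend_weeks, control_arm)
  tf <- trend_filter(prof[row_id %in% s1$row_id], min_fold, backtrack)
  oa_markers <- merge(s1[, .(row_id, direction)],
                      tf[, .(row_id, net_fold)], by = "row_id")

  arms <- setdiff(unique(manifest$treatment[manifest$role == "sample"]),
                  "none")
  if (!length(arms)) stop("no treatment arms in manifest")
  treat_volcano <- lapply(arms, function(a) {
    arm_name <- unique(manifest$arm[manifest$treatment == a])
    volcano_compare(table, runs_for(manifest, arm_name, treat_weeks[1]),
                    runs_for(manifest, arm_name, treat_weeks[2]),
                    fc_threshold, alpha)
  })
  names(treat_volcano) <- arms
  c1 <- if (length(arms) >= 2) {
    common_across_time(lapply(treat_volcano, significant_set),
                       min(allow_missing, length(arms) - 1))
  } else {
    significant_set(treat_volcano[[1]])[, .(row_id, direction,
                                            n_sets = 1L)]
  }

  # reversion: at the final week, a treated group either shows no
  # significant difference from the control arm, or has traveled at
  # least (1 - reversion_band) of the control-disease log gap away
  # from the disease level, toward the control.  Distances are
  # anchored at the disease arm, which appears on both sides of the
  # inequality, so noise in any one reference group largely cancels.
  # Required in at least half of the treatment arms.
  final_w <- treat_weeks[2]
  oa_final <- volcano_compare(table,
                              runs_for(manifest, disease_arm, final_w),
                              runs_for(manifest, control_arm, final_w),
                              fc_threshold, alpha)
  log_oa <- log(oa_final$mean_a)
  gap_sham <- log(oa_final$mean_b) - log_oa
  revert_volcano <- lapply(arms, function(a) {
    arm_name <- unique(manifest$arm[manifest$treatment == a])
    volcano_compare(table, runs_for(manifest, arm_name, final_w),
                    runs_for(manifest, control_arm, final_w),
                    fc_threshold, alpha)
  })
  names(revert_volcano) <- arms
  n_pass <- Reduce(`+`, lapply(revert_volcano, function(v) {
    dist_t <- log(v$mean_a) - log_oa
    closed <- is.finite(dist_t) & is.finite(gap_sham) &
      sign(dist_t) == sign(gap_sham) &
      abs(dist_t) >= (1 - reversion_band) * abs(gap_sham)
    as.integer(v$testable & (!(v$significant %in% TRUE) | closed))
  }))
  reverting <- table$rows$row_id[n_pass >= ceiling(length(arms) / 2)]
  curing_markers <- c1[row_id %in% reverting]

  markers <- cross_reference(oa_markers, curing_markers, table)

  structure(list(markers = markers, oa_markers = oa_markers,
                 curing_markers = curing_markers,
                 disease_volcano = disease_volcano,
                 treatment_volcano = treat_volcano,
                 reversion_volcano = revert_volcano),
            class = "cil_markers")
}

#' @export
print.cil_markers <- function(x, ...) {
  cat("CIL marker selection:", nrow(x$oa_markers), "disease markers,",
      nrow(x$curing_markers), "treatment-response markers,",
      nrow(x$markers), "final candidates\n")
  invisible(x)
}
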