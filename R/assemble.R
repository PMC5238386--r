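# Sample normalization, cross-run alignment, zero-filling, presence
# filtering: building the metabolite-intensity (ratio) table.

#' LC-UV based equal-mole normalization records
#'
#' Given per-sample total labeled-metabolite concentrations, computes
#' the relative volume of each sample that yields equal mole amounts
#' (inversely proportional to concentration, scaled so the most
#' concentrated sample has volume 1) and flags samples whose
#' concentration lies outside 50-150% of the study mean.  Flagged
#' samples are reported, not removed.
#'
#' @param totals Named numeric vector (or data.frame with
#'   `sample_id`, `total`) of total concentrations, all positive.
#' @return A data.table with `sample_id`, `total`, `factor`
#'   (total / mean), `volume` (relative volume for equal moles) and
#'   `flag`.
#' @export
lcuv_normalize <- function(totals) {
  if (is.data.frame(totals)) {
    dt <- as.data.table(totals)[, .(sample_id, total)]
  } else {
    dt <- data.table(sample_id = names(totals) %||%
                       as.character(seq_along(totals)),
                     total = as.numeric(totals))
  }
  if (any(dt$total <= 0)) stop("totals must be positive")
  dt[, factor := total / mean(total)]
  dt[, volume := max(total) / total]
  dt[, flag := factor < 0.5 | factor > 1.5]
  dt[]
}

#' Align peak pairs across runs into a ratio table
#'
#' Pairs from all runs are clustered greedily in order of descending
#' total intensity (ties by ascending m/z): a pair joins the nearest
#' row whose running intensity-weighted consensus m/z and RT lie
#' within both tolerances and that does not already hold a pair from
#' the same run; otherwise it founds a new row.  Every input pair
#' lands in exactly one row.
#'
#' @param pair_tables Named list (by run id) of quantified pair
#'   tables from [detect_pairs()].
#' @param mz_tol_ppm,rt_tol Alignment tolerances.
#' @param manifest Optional manifest data.table; fixes column order
#'   and attaches per-run metadata.
#' @return A `cil_table`: list with `rows` (consensus m/z, RT, tag
#'   count per aligned row), `ratios` (rows x runs matrix of
#'   chromatographic ratios), `provenance` (character matrix:
#'   `"detected"`, `"zero_filled"` or `"missing"`) and `runs`
#'   (column metadata).
#' @export
align_runs <- function(pair_tables, mz_tol_ppm = 10, rt_tol = 20,
                       manifest = NULL) {
  stopifnot(length(pair_tables) >= 1, !is.null(names(pair_tables)))
  run_ids <- if (!is.null(manifest)) manifest$run_id else
    names(pair_tables)
  stopifnot(all(names(pair_tables) %in% run_ids))

  all_pairs <- rbindlist(lapply(names(pair_tables), function(rid) {
    p <- pair_tables[[rid]]
    if (nrow(p) == 0) return(NULL)
    data.table(run = rid, mz = p$pair_mz, rt = p$rt, n_tags = p$n_tags,
               intensity = p$intensity, ratio = p$chrom_ratio)
  }))
  if (is.null(all_pairs) || nrow(all_pairs) == 0) {
    stop("no pairs to align")
  }
  all_pairs <- all_pairs[is.finite(ratio) & ratio > 0]
  all_pairs[, run_i := match(run, run_ids)]
  setorder(all_pairs, -intensity, mz)

  row_of <- align_pairs_cpp(all_pairs$mz, all_pairs$rt,
                            all_pairs$intensity, all_pairs$run_i,
                            length(run_ids), mz_tol_ppm, rt_tol)
  all_pairs[, row := row_of]

  rows <- all_pairs[, .(
    mz = sum(mz * intensity) / sum(intensity),
    rt = sum(rt * intensity) / sum(intensity),
    n_tags = {
      tb <- table(n_tags)
      as.integer(names(tb)[which.max(tb)])
    },
    n_members = .N
  ), by = row]
  setorder(rows, mz)
  newid <- seq_len(nrow(rows))
  remap <- integer(max(rows$row))
  remap[rows$row] <- newid
  rows[, row_id := sprintf("row%04d", newid)]
  rows[, row := NULL]

  ratios <- matrix(NA_real_, nrow(rows), length(run_ids),
                   dimnames = list(rows$row_id, run_ids))
  prov <- matrix("missing", nrow(rows), length(run_ids),
                 dimnames = list(rows$row_id, run_ids))
  ij <- cbind(remap[all_pairs$row], all_pairs$run_i)
  ratios[ij] <- all_pairs$ratio
  prov[ij] <- "detected"

  runs <- if (!is.null(manifest)) copy(manifest) else
    data.table(run_id = run_ids)

  structure(list(rows = rows[], ratios = ratios, provenance = prov,
                 runs = runs),
            class = "cil_table")
}

#' @export
print.cil_table <- function(x, ...) {
  pv <- table(factor(x$provenance,
                     c("detected", "zero_filled", "missing")))
  cat("CIL ratio table: ", nrow(x$rows), " aligned pairs x ",
      ncol(x$ratios), " runs (", pv[["detected"]], " detected, ",
      pv[["zero_filled"]], " zero-filled, ", pv[["missing"]],
      " missing cells)\n", sep = "")
  invisible(x)
}

#' Zero-fill missing ratio-table cells from raw centroid data
#'
#' For each missing cell, the raw centroids of that run are
#' re-searched at the row's consensus m/z (light channel, and
#' `n_tags x 2.00671` Da higher for the heavy channel) within the ppm
#' tolerance and an RT window around the consensus apex, using a
#' relaxed intensity threshold (`relaxed_sn` times the run noise
#' level instead of the full picking threshold).  When both channels
#' are found with at least `min_scans` scans each, the cell is filled
#' with the light/heavy area ratio and provenance `"zero_filled"`.
#' Detected cells are never modified, so completeness is monotone
#' non-decreasing.
#'
#' @param table A `cil_table`.
#' @param runs Named list of `cil_run` objects, or a directory of
#'   centroid CSV files named `<run_id>.csv`.
#' @param params The [pair_params()] used for detection.
#' @param rt_window RT half-window around the consensus apex, s.
#' @param relaxed_sn Relaxed S/N multiple for the re-search.
#' @param min_scans Minimum scans per channel to accept a fill.
#' @return The table with filled cells.
#' @export
zero_fill <- function(table, runs, params = pair_params(),
                      rt_window = 15, relaxed_sn = 1, min_scans = 3) {
  stopifnot(inherits(table, "cil_table"))
  cc <- chem_constants()
  run_ids <- colnames(table$ratios)
  from_dir <- is.character(runs) && length(runs) == 1
  if (!from_dir && !all(run_ids %in% names(runs))) {
    stop("missing raw run(s): ",
         paste(setdiff(run_ids, names(runs)), collapse = ", "))
  }

  rows <- table$rows
  mz_l <- rows$mz
  mz_h <- rows$mz + rows$n_tags * cc$tag_delta
  tol <- params$mz_tol_ppm * 1e-6 * rows$mz

  for (ci in seq_along(run_ids)) {
    miss <- which(table$provenance[, ci] == "missing")
    if (!length(miss)) next
    rid <- run_ids[ci]
    run <- if (from_dir) {
      path <- file.path(runs, paste0(rid, ".csv"))
      if (!file.exists(path)) stop("missing raw run file: ", path)
      read_run_csv(path)
    } else runs[[rid]]
    cent <- as.data.table(run)[, .(rt, mz, intensity)]
    floor_i <- relaxed_sn * .estimate_noise(cent, params)
    setorder(cent, mz)
    mzv <- cent$mz

    for (r in miss) {
      ok <- TRUE
      area <- c(NA_real_, NA_real_)
      for (ch in 1:2) {
        m0 <- if (ch == 1) mz_l[r] else mz_h[r]
        i0 <- findInterval(m0 - tol[r], mzv)
        i1 <- findInterval(m0 + tol[r], mzv)
        if (i1 <= i0) { ok <- FALSE; break }
        sl <- cent[(i0 + 1):i1][abs(rt - rows$rt[r]) <= rt_window &
                                  intensity >= floor_i]
        if (uniqueN(sl$rt) < min_scans) { ok <- FALSE; break }
        area[ch] <- sum(sl$intensity)
      }
      if (ok && area[2] > 0) {
        table$ratios[r, ci] <- area[1] / area[2]
        table$provenance[r, ci] <- "zero_filled"
      }
    }
  }
  table
}

#' Presence filter on the ratio table
#'
#' Keeps rows observed in strictly more than `fraction` of the
#' sample runs ("more than 50%" is a strict inequality).  QC columns
#' are excluded from the presence count when run roles are known.
#' Zero-filled cells count as present by default.  Idempotent.
#'
#' @param table A `cil_table`.
#' @param fraction Presence fraction threshold in (0, 1).
#' @param count_zero_filled Count zero-filled cells as present.
#' @return The filtered `cil_table`.
#' @export
presence_filter <- function(table, fraction = 0.5,
                            count_zero_filled = TRUE) {
  stopifnot(inherits(table, "cil_table"),
            fraction > 0, fraction < 1)
  cols <- if ("role" %in% names(table$runs)) {
    which(table$runs$role == "sample")
  } else {
    seq_len(ncol(table$ratios))
  }
  present <- table$provenance[, cols, drop = FALSE] == "detected"
  if (count_zero_filled) {
    present <- present |
      table$provenance[, cols, drop = FALSE] == "zero_filled"
  }
  keep <- rowSums(present) > fraction * length(cols)
  table$rows <- table$rows[keep]
  table$ratios <- table$ratios[keep, , drop = FALSE]
  table$provenance <- table$provenance[keep, , drop = FALSE]
  table
}

#' Extract the ratio matrix of selected runs
#'
#' @param table A `cil_table`.
#' @param runs Optional run ids (default all columns).
#' @return Numeric matrix rows x runs with NA for missing cells.
#' @export
ratio_matrix <- function(table, runs = NULL) {
  m <- table$ratios
  if (!is.null(runs)) m <- m[, runs, drop = FALSE]
  m
}

#' Run ids of a given (arm, week) group
#'
#' @param manifest A design manifest.
#' @param arm Arm name.
#' @param week Week number (ignored with NA for QC).
#' @param role Run role to select.
#' @return Character vector of run ids.
#' @export
runs_for <- function(manifest, arm, week = NULL, role = "sample") {
  df <- as.data.frame(manifest)
  sel <- df$role == role
  if (!is.null(arm)) sel <- sel & df$arm == arm
  if (!is.null(week)) sel <- sel & !is.na(df$week) & df$week == week
  df$run_id[sel]
}
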