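# Tiered metabolite annotation: positive identification against a
# dansyl standard library (mass + RT), then mass-only matching.

#' Load the bundled dansyl standard library
#'
#' A small demonstration library of named dansylated standards with
#' masses computed from their molecular formulas.  The retention
#' times are synthetic placeholders on the simulated RT axis (real
#' standard libraries normalize RT to a reference run); supply your
#' own CSV for real data.
#'
#' @param path CSV with columns `name`, `formula` (or
#'   `neutral_mass`), `tag_count`, `rt_s`.
#' @return A data.table with `name`, `neutral_mass`, `tag_count`,
#'   `rt_s`.
#' @export
load_dansyl_library <- function(path = system.file(
  "extdata", "dansyl_standards_synthetic.csv", package = "cilquant")) {
  lib <- fread(path)
  if (!"neutral_mass" %in% names(lib)) {
    lib[, neutral_mass := monoisotopic_mass(formula)]
  }
  stopifnot(all(lib$neutral_mass > 0), all(lib$tag_count >= 1))
  lib[, .(name, neutral_mass, tag_count, rt_s)]
}

#' Load a mass-only metabolite library
#'
#' @param path CSV with columns `name` and `formula` (or
#'   `neutral_mass`).
#' @return A data.table with `name` and `neutral_mass`.
#' @export
load_mass_library <- function(path = system.file(
  "extdata", "mass_library_primary.csv", package = "cilquant")) {
  lib <- fread(path)
  if (!"neutral_mass" %in% names(lib)) {
    lib[, neutral_mass := monoisotopic_mass(formula)]
  }
  lib[, .(name, neutral_mass)]
}

#' Positive identification against a dansyl standard library
#'
#' A row is identified when its observed light m/z lies within
#' `mass_tol_ppm` of the labeled, protonated standard m/z AND its
#' retention time within `rt_tol` of the library RT.  All qualifying
#' entries are listed, sorted by absolute ppm error.
#'
#' @param table A `cil_table` (or its `rows` data.table).
#' @param library Output of [load_dansyl_library()].
#' @param mass_tol_ppm,rt_tol Match tolerances (10 ppm, 60 s).
#' @return A data.table of candidates: `row_id`, `name`,
#'   `ppm_error`, `rt_error`.
#' @export
match_library <- function(table, library, mass_tol_ppm = 10,
                          rt_tol = 60) {
  stopifnot(nrow(library) > 0)
  rows <- if (inherits(table, "cil_table")) table$rows else
    as.data.table(table)
  lib <- copy(library)
  lib[, theo_mz := labeled_mz(neutral_mass, tag_count, "light")]
  hits <- rbindlist(lapply(seq_len(nrow(rows)), function(i) {
    ppm <- (rows$mz[i] - lib$theo_mz) / rows$mz[i] * 1e6
    dr <- rows$rt[i] - lib$rt_s
    sel <- abs(ppm) <= mass_tol_ppm & abs(dr) <= rt_tol
    if (!any(sel)) return(NULL)
    data.table(row_id = rows$row_id[i], name = lib$name[sel],
               ppm_error = ppm[sel], rt_error = dr[sel])
  }))
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.table(row_id = character(0), name = character(0),
                      ppm_error = numeric(0), rt_error = numeric(0)))
  }
  hits[order(row_id, abs(ppm_error))]
}

#' Mass-only matching against a metabolite mass library
#'
#' The neutral mass recovered from a row's light m/z and tag count
#' (strip one proton and `n_tags` dansyl additions) is compared to
#' the library masses within `mass_tol_ppm`.
#'
#' @param table A `cil_table` (or its `rows`; needs `n_tags`).
#' @param library Output of [load_mass_library()].
#' @param mass_tol_ppm Mass tolerance, ppm.
#' @return A data.table of candidates: `row_id`, `name`, `ppm_error`.
#' @export
match_mass <- function(table, library, mass_tol_ppm = 10) {
  rows <- if (inherits(table, "cil_table")) table$rows else
    as.data.table(table)
  hits <- rbindlist(lapply(seq_len(nrow(rows)), function(i) {
    rec <- recovered_neutral_mass(rows$mz[i], rows$n_tags[i])
    ppm <- (rec - library$neutral_mass) / rec * 1e6
    sel <- abs(ppm) <= mass_tol_ppm
    if (!any(sel)) return(NULL)
    data.table(row_id = rows$row_id[i], name = library$name[sel],
               ppm_error = ppm[sel])
  }))
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.table(row_id = character(0), name = character(0),
                      ppm_error = numeric(0)))
  }
  hits[order(row_id, abs(ppm_error))]
}

#' Tiered annotation of a ratio table
#'
#' Tier precedence: `identified` (dansyl library, mass + RT) >
#' `mass_matched_primary` (known-metabolite mass library) >
#' `mass_matched_predicted` (predicted-metabolite mass library) >
#' `unknown`.  Each row receives exactly one tier, the best that has
#' at least one candidate.
#'
#' @param table A `cil_table`.
#' @param dansyl_lib,primary_lib,predicted_lib Libraries (predicted
#'   may be NULL).
#' @param mass_tol_ppm,rt_tol Tolerances.
#' @return A data.table `row_id`, `tier`, `top_match`,
#'   `n_candidates`; all candidate lists are kept in the
#'   `"candidates"` attribute.
#' @export
annotate_table <- function(table, dansyl_lib = load_dansyl_library(),
                           primary_lib = load_mass_library(),
                           predicted_lib = NULL,
                           mass_tol_ppm = 10, rt_tol = 60) {
  rows <- table$rows
  idh <- match_library(table, dansyl_lib, mass_tol_ppm, rt_tol)
  prh <- match_mass(table, primary_lib, mass_tol_ppm)
  pdh <- if (!is.null(predicted_lib)) {
    match_mass(table, predicted_lib, mass_tol_ppm)
  } else {
    data.table(row_id = character(0), name = character(0),
               ppm_error = numeric(0))
  }

  out <- data.table(row_id = rows$row_id, tier = "unknown",
                    top_match = NA_character_, n_candidates = 0L)
  fill <- function(out, hits, tiername) {
    if (nrow(hits) == 0) return(out)
    top <- hits[, .(top_match = name[1], n_candidates = .N), by = row_id]
    sel <- out$tier == "unknown" & out$row_id %in% top$row_id
    idx <- match(out$row_id[sel], top$row_id)
    out[sel, `:=`(tier = tiername, top_match = top$top_match[idx],
                  n_candidates = top$n_candidates[idx])]
    out
  }
  out <- fill(out, idh, "identified")
  out <- fill(out, prh, "mass_matched_primary")
  out <- fill(out, pdh, "mass_matched_predicted")
  setattr(out, "candidates",
          list(identified = idh, mass_matched_primary = prh,
               mass_matched_predicted = pdh))
  out[]
}
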