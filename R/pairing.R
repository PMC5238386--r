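# 12C/13C peak-pair detection and ratio quantification.

#' Detect 12C/13C peak pairs among the features of one run
#'
#' A pair is emitted when a heavier feature sits `n x 2.00671` Da
#' (n in `n_tags_range`) above a lighter feature within `mz_tol_ppm`
#' (relative to the light m/z, inclusive) and the two apexes co-elute
#' within `rt_coelution_tol`.  Candidate light features that are
#' themselves one 13C spacing (+1.003355 Da) above a stronger
#' co-eluting feature are excluded as natural-isotope satellites.
#' Each feature joins at most one pair: candidates are ranked by
#' summed area (ties by lower light m/z, then fewer tags) and
#' assigned greedily.
#'
#' @param feats A `cil_features` object (or its `features` table).
#' @param params A [pair_params()].
#' @return A data.table of pairs: `light`, `heavy` (feature ids),
#'   `n_tags`, `pair_mz` (light m/z), `rt` (light apex),
#'   `delta_ppm` (deviation of the observed spacing from
#'   `n_tags x tag_delta`, in ppm of the light m/z) and `intensity`
#'   (summed area).
#' @export
pair_features <- function(feats, params = pair_params()) {
  ft <- if (inherits(feats, "cil_features")) feats$features else
    as.data.table(feats)
  cc <- chem_constants()
  empty <- data.table(light = integer(0), heavy = integer(0),
                      n_tags = integer(0), pair_mz = numeric(0),
                      rt = numeric(0), delta_ppm = numeric(0),
                      intensity = numeric(0))
  if (nrow(ft) < 2) return(empty)
  setorder(ft, mz)

  tol <- params$mz_tol_ppm * 1e-6 * ft$mz

  # natural-isotope exclusion: is there a stronger co-eluting feature
  # one 13C spacing below?
  iso_target <- ft$mz - params$isotope_delta
  lo <- findInterval(iso_target - tol, ft$mz)
  hi <- findInterval(iso_target + tol, ft$mz)
  excluded <- vapply(seq_len(nrow(ft)), function(i) {
    if (hi[i] <= lo[i]) return(FALSE)
    j <- (lo[i] + 1):hi[i]
    any(ft$height[j] > ft$height[i] &
          abs(ft$rt[j] - ft$rt[i]) <= params$rt_coelution_tol)
  }, logical(1))

  cand <- list()
  for (n in params$n_tags_range) {
    target <- ft$mz + n * cc$tag_delta
    lo <- findInterval(target - tol, ft$mz)
    hi <- findInterval(target + tol, ft$mz)
    cnt <- pmax(0L, hi - lo)
    li <- rep.int(seq_len(nrow(ft)), cnt)
    if (!length(li)) next
    hj <- unlist(lapply(which(cnt > 0), function(i) (lo[i] + 1):hi[i]))
    ok <- !excluded[li] & hj != li &
      abs(ft$rt[hj] - ft$rt[li]) <= params$rt_coelution_tol
    if (any(ok)) {
      cand[[length(cand) + 1]] <- data.table(
        light = li[ok], heavy = hj[ok], n_tags = n)
    }
  }
  if (!length(cand)) return(empty)
  cand <- rbindlist(cand)
  cand[, intensity := ft$area[light] + ft$area[heavy]]
  cand[, pair_mz := ft$mz[light]]
  setorder(cand, -intensity, pair_mz, n_tags)

  used <- logical(nrow(ft))
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    l <- cand$light[k]; h <- cand$heavy[k]
    if (!used[l] && !used[h]) {
      used[l] <- used[h] <- TRUE
      take[k] <- TRUE
    }
  }
  pairs <- cand[take]
  pairs[, rt := ft$rt[light]]
  pairs[, delta_ppm :=
          (ft$mz[heavy] - ft$mz[light] - n_tags * cc$tag_delta) /
          pair_mz * 1e6]
  pairs[, light := ft$feature[light]]
  pairs[, heavy := ft$feature[heavy]]
  setorder(pairs, pair_mz)
  pairs[, .(light, heavy, n_tags, pair_mz, rt, delta_ppm, intensity)]
}

#' Quantify peak pairs by MS and chromatographic ratios
#'
#' For each pair the chromatographic ratio is the light area divided
#' by the heavy area over the intersection of the two peaks' RT
#' windows, and the MS ratio is the light/heavy intensity at the
#' shared apex scan (the scan with the largest summed light + heavy
#' intensity inside the shared window).
#'
#' @param pairs Output of [pair_features()].
#' @param feats The `cil_features` object the pairs came from (its
#'   centroid profiles are needed).
#' @return `pairs` with `ms_ratio` and `chrom_ratio` columns added;
#'   pairs whose heavy channel has zero area in the shared window are
#'   dropped with a warning.
#' @export
quantify_pairs <- function(pairs, feats) {
  stopifnot(inherits(feats, "cil_features"))
  if (nrow(pairs) == 0) {
    pairs[, `:=`(ms_ratio = numeric(0), chrom_ratio = numeric(0))]
    return(pairs[])
  }
  cent <- feats$centroids
  ft <- feats$features

  pid <- seq_len(nrow(pairs))
  win_lo <- pmax(ft$rt_start[pairs$light], ft$rt_start[pairs$heavy])
  win_hi <- pmin(ft$rt_end[pairs$light], ft$rt_end[pairs$heavy])

  prof <- cent[!is.na(feature),
               .(intensity = sum(intensity)), by = .(feature, rt)]
  lp <- prof[data.table(feature = pairs$light, pair = pid),
             on = "feature", allow.cartesian = TRUE]
  hp <- prof[data.table(feature = pairs$heavy, pair = pid),
             on = "feature", allow.cartesian = TRUE]
  lp <- lp[rt >= win_lo[pair] & rt <= win_hi[pair]]
  hp <- hp[rt >= win_lo[pair] & rt <= win_hi[pair]]

  aa <- merge(lp[, .(area_l = sum(intensity)), by = pair],
              hp[, .(area_h = sum(intensity)), by = pair], by = "pair")
  m <- merge(lp[, .(pair, rt, l = intensity)],
             hp[, .(pair, rt, h = intensity)], by = c("pair", "rt"))
  qq <- m[, {
    apex <- which.max(l + h)
    .(ms_ratio = l[apex] / h[apex])
  }, by = pair]

  out <- copy(pairs)
  out[, ms_ratio := NA_real_]
  out[, chrom_ratio := NA_real_]
  out[aa$pair, chrom_ratio := aa$area_l / aa$area_h]
  out[qq$pair, ms_ratio := qq$ms_ratio]
  bad <- !is.finite(out$chrom_ratio) | out$chrom_ratio <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) dropped: zero heavy area or empty ",
            "shared window")
    out <- out[!bad]
  }
  out[]
}

#' Detect and quantify the peak pairs of one run
#'
#' Convenience wrapper: [extract_features()], [pair_features()],
#' [quantify_pairs()].
#'
#' @param run A `cil_run`.
#' @param params A [pair_params()].
#' @return Quantified pair table (see [quantify_pairs()]).
#' @export
detect_pairs <- function(run, params = pair_params()) {
  feats <- extract_features(run, params)
  quantify_pairs(pair_features(feats, params), feats)
}
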