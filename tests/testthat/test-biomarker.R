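# Time-course marker selection logic.

mk_set <- function(ids, dir = 1) {
  data.table(row_id = ids, direction = dir, fold_change = 2)
}

test_that("cross-time intersection honors the one-missing tolerance", {
  sets <- list(mk_set(c("A", "B", "C")), mk_set(c("A", "B")),
               mk_set(c("A", "C")))
  expect_setequal(common_across_time(sets, 1)$row_id, c("A", "B", "C"))
  expect_equal(common_across_time(sets, 0)$row_id, "A")
  expect_error(common_across_time(sets, 3), "allow_missing")
  expect_error(common_across_time(sets[1], 0), "at least 2")
})

test_that("direction conflicts exclude a row", {
  sets <- list(mk_set("A", 1), mk_set("A", 1), mk_set("A", -1))
  expect_equal(nrow(common_across_time(sets, 1)), 0)
})

test_that("trend filter passes gradual changes and rejects flat or
           erratic ones", {
  weeks <- c(0, 2, 4, 6)
  prof <- rbindlist(list(
    data.table(row_id = "up", week = weeks,
               mean = c(1, 1.5, 1.8, 2), sd = 0.1, n = 6),
    data.table(row_id = "down", week = weeks,
               mean = c(1, 0.7, 0.6, 0.5), sd = 0.1, n = 6),
    data.table(row_id = "flat", week = weeks,
               mean = c(1, 1.02, 0.99, 1.01), sd = 0.1, n = 6),
    data.table(row_id = "zigzag", week = weeks,
               mean = c(1, 1.9, 0.8, 1.6), sd = 0.1, n = 6)
  ))
  res <- trend_filter(prof)
  expect_setequal(res$row_id, c("up", "down"))
  expect_equal(res[row_id == "up", direction], 1)
  expect_equal(res[row_id == "down", direction], -1)
  expect_error(trend_filter(prof[week <= 2]), ">= 3 weeks")
})

test_that("randomly fluctuating trajectories rarely pass the trend
           filter", {
  # profiles drifting at the default random-class sigma (0.10 per
  # group) with no systematic trend
  set.seed(99)
  n_pass <- 0
  for (i in 1:400) {
    prof <- data.table(row_id = "r", week = c(0, 2, 4, 6),
                       mean = exp(rnorm(4, 0, 0.10)), sd = 0.1, n = 6)
    n_pass <- n_pass + nrow(trend_filter(prof))
  }
  expect_lt(n_pass / 400, 0.1)
})

test_that("cross-reference intersects, checks direction and ranks by
           completeness", {
  study <- small_study()
  tab <- study$table
  ids <- tab$rows$row_id
  oa <- mk_set(ids[1:4])[, net_fold := c(3, 2, 2.5, 1.5)]
  cu <- mk_set(ids[3:6])
  res <- cross_reference(oa, cu, tab)
  expect_setequal(res$row_id, ids[3:4])
  expect_true(all(res$completeness_runs >= 0 &
                    res$completeness_runs <= 1))
  expect_true(all(diff(res$completeness_runs) <= 0))
  # direction conflict removes the row
  cu2 <- copy(cu)[row_id == ids[3], direction := -1]
  expect_false(ids[3] %in% cross_reference(oa, cu2, tab)$row_id)
  # disjoint and subset cases
  expect_equal(nrow(cross_reference(mk_set("x"), mk_set("y"), tab)), 0)
  sub <- cross_reference(oa, oa[1:2], tab)
  expect_setequal(sub$row_id, oa$row_id[1:2])
})

test_that("venn counts enumerate exclusive regions summing to the
           union", {
  v <- venn_counts(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(v[["A"]], 1)
  expect_equal(v[["B"]], 1)
  expect_equal(v[["A&B"]], 1)
  expect_equal(sum(v), 3)
  v2 <- venn_counts(list(A = 1:5, B = 1:5))
  expect_equal(unname(v2), c(0, 0, 5))
  expect_error(venn_counts(list(1:2)), "2 to 4")
  # brute-force oracle on random sets
  set.seed(12)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(j) sample(1:20, sample(0:15, 1)))
    names(sets) <- LETTERS[seq_len(k)]
    v <- venn_counts(sets)
    uni <- unique(unlist(sets))
    # recompute every region by direct membership enumeration
    for (rg in names(v)) {
      inset <- strsplit(rg, "&")[[1]]
      outset <- setdiff(names(sets), inset)
      cnt <- sum(vapply(uni, function(e) {
        all(vapply(inset, function(s) e %in% sets[[s]], logical(1))) &&
          !any(vapply(outset, function(s) e %in% sets[[s]],
                      logical(1)))
      }, logical(1)))
      expect_equal(unname(v[rg]), cnt)
    }
    expect_equal(sum(v), length(uni))
  }
})

test_that("the selection pipeline recovers the planted markers on the
           small study with no false positives", {
  study <- small_study()
  mk <- select_markers(study$table)
  planted <- planted_rows(study)
  # the 4-rat study has less power than the full design, so demand
  # zero false positives and most of the planted markers
  expect_true(all(mk$markers$row_id %in% planted))
  expect_gte(nrow(mk$markers), length(planted) - 1)
  # reported directions match the planted (rising) trajectories
  expect_true(all(mk$markers$direction == 1))
})
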