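# PCA, OPLS-DA and volcano statistics.

sim_matrix <- function(n = 24, p = 40, shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, sd = sd), n, p)
  y <- rep(c(0, 1), each = n / 2)
  X[, 1:5] <- X[, 1:5] + shift * y
  list(X = scale(X, scale = FALSE), y = y)
}

test_that("PCA reproduces SVD variance shares and orthogonal loadings", {
  d <- sim_matrix(20, 15, seed = 2)
  pc <- cil_pca(d$X, k = 5, cv_folds = 0)
  sv <- svd(d$X)
  expect_equal(pc$r2x, cumsum(sv$d[1:5]^2) / sum(sv$d^2),
               tolerance = 1e-8)
  g <- crossprod(pc$loadings)
  expect_equal(g, diag(5), tolerance = 1e-8)
  # full-rank decomposition explains everything
  pcf <- cil_pca(d$X, k = 19, cv_folds = 0)
  expect_equal(pcf$r2x[length(pcf$r2x)], 1, tolerance = 1e-8)
  expect_error(cil_pca(matrix(0, 5, 3)), "all-constant")
})

test_that("planted cluster separation appears on PC1", {
  d <- sim_matrix(30, 40, shift = 5, seed = 3)
  pc <- cil_pca(d$X, k = 2, cv_folds = 0)
  s1 <- pc$scores[, 1]
  # classes linearly separable on the first score
  m0 <- s1[d$y == 0]; m1 <- s1[d$y == 1]
  expect_true(max(m0) < min(m1) || max(m1) < min(m0))
})

test_that("cross-validated Q2 is high for structured data", {
  d <- sim_matrix(28, 30, shift = 6, seed = 4)
  pc <- cil_pca(d$X, k = 2, cv_folds = 7)
  expect_gt(pc$q2[1], 0)
})

test_that("OPLS-DA separates well-separated classes with high Q2", {
  d <- sim_matrix(24, 40, shift = 4, seed = 5)
  m <- cil_oplsda(d$X, d$y, n_orthogonal = 1)
  expect_gt(m$q2, 0.5)
  expect_lte(m$q2, m$r2y + 1e-8)
  expect_true(m$r2x >= 0 && m$r2x <= 1)
  # scores separate the classes
  expect_true(abs(mean(m$t[d$y == 1]) - mean(m$t[d$y == 0])) >
                2 * max(sd(m$t[d$y == 1]), sd(m$t[d$y == 0])))
})

test_that("OPLS-DA with no orthogonal component equals 1-component
           PLS-DA", {
  skip_if_not_installed("mixOmics")
  d <- sim_matrix(24, 30, shift = 2, seed = 6)
  m <- cil_oplsda(d$X, d$y, n_orthogonal = 0, cv_folds = 0)
  ref <- mixOmics::plsda(d$X, factor(d$y), ncomp = 1, scale = FALSE)
  r <- cor(m$t, ref$variates$X[, 1])
  expect_equal(abs(as.numeric(r)), 1, tolerance = 1e-6)
})

test_that("a strong class-irrelevant direction is captured by the
           orthogonal component", {
  set.seed(7)
  n <- 30; p <- 40
  y <- rep(c(0, 1), each = n / 2)
  conf_dir <- rnorm(p); conf_dir <- conf_dir / sqrt(sum(conf_dir^2))
  sig_dir <- rep(0, p); sig_dir[1:5] <- 1 / sqrt(5)
  conf_score <- rnorm(n, sd = 8)              # independent of y
  X <- outer(2 * (y - 0.5), sig_dir) * 3 +
    outer(conf_score, conf_dir) + matrix(rnorm(n * p, sd = 0.5), n, p)
  X <- scale(X, scale = FALSE)
  m <- cil_oplsda(X, y, n_orthogonal = 1, cv_folds = 0)
  w <- m$weights / sqrt(sum(m$weights^2))
  expect_lt(abs(sum(w * conf_dir)), 0.2)
  expect_gt(abs(cor(m$t_orth[, 1], conf_score)), 0.8)
})

test_that("permuted labels give Q2 at or below chance", {
  d <- sim_matrix(24, 30, shift = 3, seed = 8)
  q2p <- oplsda_permutation(d$X, d$y, n_perm = 40, seed = 9)
  expect_lte(mean(q2p), 0.05)
})

test_that("OPLS-DA validates its label input", {
  d <- sim_matrix(12, 10, seed = 10)
  expect_error(cil_oplsda(d$X, rep(1, 12)), "two classes")
  expect_error(cil_oplsda(d$X, c(rep(0, 10), 1, 1)), ">= 3")
})

null_table <- function(n_rows, n_a, n_b, sdlog = 0.1, shift = 1,
                       seed = 1) {
  set.seed(seed)
  runs <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  ratios <- matrix(rlnorm(n_rows * (n_a + n_b), 0, sdlog), n_rows,
                   dimnames = list(sprintf("row%04d", seq_len(n_rows)),
                                   runs))
  ratios[, seq_len(n_a)] <- ratios[, seq_len(n_a)] * shift
  structure(list(
    rows = data.table(row_id = rownames(ratios)),
    ratios = ratios,
    provenance = matrix("detected", n_rows, n_a + n_b,
                        dimnames = dimnames(ratios)),
    runs = data.table(run_id = runs, role = "sample")),
    class = "cil_table")
}

test_that("volcano flags a planted two-fold shift", {
  tab <- null_table(50, 6, 6, sdlog = 0.15, seed = 11)
  tab$ratios[1:5, 1:6] <- tab$ratios[1:5, 1:6] * 2
  v <- volcano_compare(tab, paste0("a", 1:6), paste0("b", 1:6))
  expect_true(all(v$significant[1:5]))
  expect_true(all(v$direction[1:5] == 1))
})

test_that("fold changes below threshold are never significant", {
  tab <- null_table(200, 8, 8, sdlog = 0.05, shift = 1.1, seed = 12)
  v <- volcano_compare(tab, paste0("a", 1:8), paste0("b", 1:8))
  # p-values are tiny but the 1.2-fold prong blocks significance
  expect_lt(min(v$p_value), 0.001)
  expect_false(any(v$significant))
})

test_that("null false-positive rate stays at or below alpha", {
  tab <- null_table(1000, 6, 6, sdlog = 0.1, seed = 13)
  v <- volcano_compare(tab, paste0("a", 1:6), paste0("b", 1:6))
  expect_lte(mean(v$significant), 0.05)
})

test_that("rows with too few observations are reported untestable", {
  tab <- null_table(5, 6, 6, seed = 14)
  tab$ratios[1, 1:5] <- NA
  v <- volcano_compare(tab, paste0("a", 1:6), paste0("b", 1:6),
                       min_n = 2)
  expect_false(v$testable[1])
  expect_true(is.na(v$significant[1]))
})

test_that("half-minimum imputation and scaling produce a complete
           unit-variance matrix", {
  tab <- null_table(30, 5, 5, seed = 15)
  tab$ratios[3, 2] <- NA
  tab$provenance[3, 2] <- "missing"
  X <- preprocess_matrix(tab)
  expect_false(anyNA(X))
  expect_equal(unname(apply(X, 2, sd)), rep(1, 30), tolerance = 1e-8)
  expect_equal(unname(colMeans(X)), rep(0, 30), tolerance = 1e-12)
})
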