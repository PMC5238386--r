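# Multivariate models (PCA, OPLS-DA) and volcano comparisons on the
# ratio table.

#' Preprocessing specification for multivariate models
#'
#' Missing cells are imputed (default: half the row minimum, the
#' standard treatment of left-censored metabolomics missingness),
#' ratios are log-transformed, and variables are mean-centered and
#' scaled (default: unit variance, the SIMCA convention).
#'
#' @param imputation `"half_minimum"`, `"row_mean"` or `"none"`.
#' @param log_transform Log-transform ratios before scaling.
#' @param scaling `"unit_variance"`, `"pareto"` or `"none"`
#'   (centering is always applied).
#' @return A list of class `cil_preprocess`.
#' @export
preprocess_spec <- function(imputation = c("half_minimum", "row_mean",
                                           "none"),
                            log_transform = TRUE,
                            scaling = c("unit_variance", "pareto",
                                        "none")) {
  structure(list(imputation = match.arg(imputation),
                 log_transform = log_transform,
                 scaling = match.arg(scaling)),
            class = "cil_preprocess")
}

#' Build the samples-by-variables model matrix from a ratio table
#'
#' @param table A `cil_table` or a rows-by-runs numeric matrix.
#' @param spec A [preprocess_spec()].
#' @param runs Optional run ids to keep as observations (default: all
#'   sample-role runs if roles are known).
#' @return A numeric matrix, observations (runs) in rows, aligned
#'   pairs in columns, centered and scaled per `spec`.
#' @export
preprocess_matrix <- function(table, spec = preprocess_spec(),
                              runs = NULL) {
  m <- if (inherits(table, "cil_table")) {
    if (is.null(runs) && "role" %in% names(table$runs)) {
      runs <- table$runs$run_id[table$runs$role == "sample"]
    }
    ratio_matrix(table, runs)
  } else {
    as.matrix(table)
  }
  if (spec$imputation == "half_minimum") {
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (any(miss) && !all(miss)) {
        m[i, miss] <- min(m[i, !miss]) / 2
      }
    }
  } else if (spec$imputation == "row_mean") {
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (any(miss) && !all(miss)) m[i, miss] <- mean(m[i, !miss])
    }
  }
  m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
  x <- t(m)  # observations = runs
  if (spec$log_transform) x <- log(x)
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  if (spec$scaling != "none") {
    s <- apply(x, 2, sd)
    if (spec$scaling == "pareto") s <- sqrt(s)
    s[s == 0 | !is.finite(s)] <- 1
    x <- sweep(x, 2, s, "/")
  }
  x
}

# venetian-blind fold assignment (sample i -> fold (i-1) %% k + 1)
.venetian_folds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

#' Principal component analysis with cross-validated Q2
#'
#' Components are computed by singular value decomposition of the
#' centered (optionally scaled) matrix and ordered by explained
#' variance; `r2x` is cumulative.  Q2 uses k-fold venetian-blind
#' cross-validation over observations: each held-out observation's
#' entries are predicted by leave-one-variable-out projection onto
#' the training loadings, and the pooled PRESS gives
#' `q2 = 1 - PRESS / SS`.
#'
#' @param x A `cil_table`, or a preprocessed observations x variables
#'   matrix.
#' @param k Number of components (`<=` rank).
#' @param spec [preprocess_spec()] applied when `x` is a table.
#' @param cv_folds Folds for Q2 (default 7); set to 0 to skip.
#' @return A `cil_pca`: scores, loadings, sdev, `r2x` (cumulative)
#'   and `q2` (cumulative per component).
#' @export
cil_pca <- function(x, k = 2, spec = preprocess_spec(), cv_folds = 7) {
  X <- if (inherits(x, "cil_table")) preprocess_matrix(x, spec) else {
    sweep(as.matrix(x), 2, colMeans(as.matrix(x)))
  }
  if (all(abs(X) < 1e-12)) stop("all-constant table")
  n <- nrow(X)
  k <- min(k, n - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  ss_tot <- sum(X^2)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  r2x <- cumsum(sv$d[seq_len(k)]^2) / ss_tot

  q2 <- rep(NA_real_, k)
  if (cv_folds > 1 && n > cv_folds) {
    folds <- .venetian_folds(n, cv_folds)
    press <- matrix(0, cv_folds, k)
    for (f in seq_len(cv_folds)) {
      tr <- X[folds != f, , drop = FALSE]
      te <- X[folds == f, , drop = FALSE]
      ctr <- colMeans(tr)
      tr <- sweep(tr, 2, ctr)
      te <- sweep(te, 2, ctr)
      kk <- min(k, nrow(tr) - 1L)
      P <- svd(tr, nu = 0, nv = kk)$v
      res <- te
      pred <- matrix(0, nrow(te), ncol(te))
      for (a in seq_len(k)) {
        if (a <= kk) {
          p <- P[, a]
          # leave-one-variable-out score: t_(j) = (x.p - x_j p_j)/(1 - p_j^2)
          tfull <- as.vector(res %*% p)
          num <- matrix(tfull, nrow(res), length(p)) -
            sweep(res, 2, p, "*")
          den <- 1 - p^2
          den[den < 1e-8] <- 1e-8
          tjm <- sweep(num, 2, den, "/")
          pred <- pred + sweep(tjm, 2, p, "*")
          res <- res - (res %*% p) %*% t(p)
        }
        press[f, a] <- sum((te - pred)^2)
      }
    }
    ss0 <- sum(X^2)
    q2 <- 1 - colSums(press) / ss0
  }

  structure(list(scores = scores, loadings = loadings,
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, n - 1)),
                 r2x = r2x, q2 = q2, k = k),
            class = "cil_pca")
}

# single-response O-PLS fit on preprocessed X, centered y
.opls_fit <- function(X, y, n_orth) {
  Wo <- Po <- NULL
  Xf <- X
  if (n_orth > 0) {
    Wo <- matrix(0, ncol(X), n_orth)
    Po <- matrix(0, ncol(X), n_orth)
    To <- matrix(0, nrow(X), n_orth)
    for (a in seq_len(n_orth)) {
      w <- crossprod(Xf, y)
      w <- w / sqrt(sum(w^2))
      t1 <- Xf %*% w
      p <- crossprod(Xf, t1) / sum(t1^2)
      wo <- p - as.numeric(crossprod(w, p)) * w
      nw <- sqrt(sum(wo^2))
      if (nw < 1e-12) { Wo <- Wo[, seq_len(a - 1), drop = FALSE]
        Po <- Po[, seq_len(a - 1), drop = FALSE]
        To <- To[, seq_len(a - 1), drop = FALSE]; break }
      wo <- wo / nw
      to <- Xf %*% wo
      po <- crossprod(Xf, to) / sum(to^2)
      Xf <- Xf - to %*% t(po)
      Wo[, a] <- wo; Po[, a] <- po; To[, a] <- to
    }
  } else {
    To <- matrix(0, nrow(X), 0)
  }
  w <- crossprod(Xf, y)
  w <- w / sqrt(sum(w^2))
  t1 <- Xf %*% w
  p <- crossprod(Xf, t1) / sum(t1^2)
  c1 <- as.numeric(crossprod(y, t1) / sum(t1^2))
  list(w = as.vector(w), p = as.vector(p), c = c1, t = as.vector(t1),
       Wo = Wo, Po = Po, To = To, Xf = Xf)
}

.opls_predict_t <- function(fit, Xnew) {
  if (!is.null(fit$Wo) && ncol(fit$Wo) > 0) {
    for (a in seq_len(ncol(fit$Wo))) {
      to <- Xnew %*% fit$Wo[, a]
      Xnew <- Xnew - to %*% t(fit$Po[, a])
    }
  }
  Xnew %*% fit$w
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' Fits one predictive component plus `n_orthogonal` orthogonal
#' (class-irrelevant) components by orthogonal signal correction of a
#' single-response PLS model.  With `n_orthogonal = 0` the model is
#' exactly a one-component PLS-DA.  Q2 comes from k-fold
#' venetian-blind cross-validation of the class response
#' (`1 - PRESS / SS`).
#'
#' @param x A `cil_table` or preprocessed matrix (observations x
#'   variables).
#' @param y Binary class labels (factor, character or 0/1), one per
#'   observation; both classes need at least 3 observations.
#' @param n_orthogonal Number of orthogonal components.
#' @param spec [preprocess_spec()] applied when `x` is a table.
#' @param runs Run ids (observations) when `x` is a table; must match
#'   `y` in order.
#' @param cv_folds Cross-validation folds (default 7).
#' @return A `cil_oplsda`: predictive scores `t`, orthogonal scores
#'   `t_orth`, weights/loadings, `r2x`, `r2y`, `q2` and the class
#'   coding.
#' @export
cil_oplsda <- function(x, y, n_orthogonal = 1, spec = preprocess_spec(),
                       runs = NULL, cv_folds = 7) {
  X <- if (inherits(x, "cil_table")) {
    preprocess_matrix(x, spec, runs = runs)
  } else as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (any(table(y) < 3)) stop("each class needs >= 3 observations")
  if (length(y) != nrow(X)) stop("length(y) must match observations")
  y0 <- as.numeric(y == levels(y)[2])
  ybar <- mean(y0)
  yc <- y0 - ybar

  fit <- .opls_fit(X, yc, n_orthogonal)
  yhat <- fit$t * fit$c
  ssy <- sum(yc^2)
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  ssx <- sum(X^2)
  expl <- sum(fit$t^2) * sum(fit$p^2)
  if (!is.null(fit$To) && ncol(fit$To) > 0) {
    for (a in seq_len(ncol(fit$To))) {
      expl <- expl + sum(fit$To[, a]^2) * sum(fit$Po[, a]^2)
    }
  }
  r2x <- expl / ssx

  q2 <- NA_real_
  if (cv_folds > 1 && nrow(X) > cv_folds) {
    folds <- .venetian_folds(nrow(X), cv_folds)
    press <- 0
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- yc[tr]
      if (length(unique(y0[tr])) < 2) next
      cfit <- .opls_fit(Xtr, ytr - mean(ytr), n_orthogonal)
      tte <- .opls_predict_t(cfit, X[!tr, , drop = FALSE])
      pred <- tte * cfit$c + mean(ytr)
      press <- press + sum((yc[!tr] - pred)^2)
    }
    q2 <- 1 - press / ssy
  }

  structure(list(t = fit$t, t_orth = fit$To, weights = fit$w,
                 loadings = fit$p, c = fit$c,
                 weights_orth = fit$Wo, loadings_orth = fit$Po,
                 r2x = r2x, r2y = r2y, q2 = q2,
                 levels = levels(y), y = y0, ybar = ybar),
            class = "cil_oplsda")
}

#' @export
print.cil_oplsda <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA (1 predictive + %d orthogonal): R2X = %.1f%%, R2Y = %.1f%%, Q2 = %.1f%%\n",
    if (is.null(x$t_orth)) 0 else ncol(x$t_orth),
    100 * x$r2x, 100 * x$r2y, 100 * x$q2))
  invisible(x)
}

#' Permutation null distribution of OPLS-DA Q2
#'
#' Refits the model on label permutations; a sound model's permuted
#' Q2 values scatter at or below zero.
#'
#' @param x,y,n_orthogonal,spec,runs,cv_folds As in [cil_oplsda()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of permuted Q2 values.
#' @export
oplsda_permutation <- function(x, y, n_perm = 100, n_orthogonal = 1,
                               spec = preprocess_spec(), runs = NULL,
                               cv_folds = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (inherits(x, "cil_table")) {
    preprocess_matrix(x, spec, runs = runs)
  } else as.matrix(x)
  vapply(seq_len(n_perm), function(i) {
    yp <- sample(y)
    cil_oplsda(X, yp, n_orthogonal = n_orthogonal,
               cv_folds = cv_folds)$q2
  }, numeric(1))
}

#' Volcano comparison of two run groups
#'
#' For each aligned pair, the fold change is the larger of
#' `mean(A)/mean(B)` and its reciprocal (ratios are averaged on the
#' natural scale, matching how peak-ratio fold changes are reported),
#' the p-value comes from a two-sample t-test on log ratios (Welch by
#' default), and a pair is significant when `fold_change >=
#' fc_threshold` AND `p <= alpha`.  No multiple-testing correction is
#' applied by default; `p_adjust = "BH"` switches the significance
#' rule to FDR-adjusted p-values.
#'
#' @param table A `cil_table`.
#' @param runs_a,runs_b Run ids of the two groups.
#' @param fc_threshold,alpha Significance thresholds (1.2-fold,
#'   0.05).
#' @param var_equal Use the pooled-variance Student test instead of
#'   Welch.
#' @param min_n Minimum observed ratios per group; rows below it are
#'   reported as untestable (`testable = FALSE`, `significant = NA`).
#' @param p_adjust `"none"` or a method for [stats::p.adjust()].
#' @return A data.table: `row_id`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `fold_change`, `direction` (+1 when A > B), `p_value`,
#'   `testable`, `significant`.
#' @export
volcano_compare <- function(table, runs_a, runs_b, fc_threshold = 1.2,
                            alpha = 0.05, var_equal = FALSE,
                            min_n = 2, p_adjust = "none") {
  a <- ratio_matrix(table, runs_a)
  b <- ratio_matrix(table, runs_b)
  out <- data.table(row_id = table$rows$row_id)
  res <- lapply(seq_len(nrow(out)), function(i) {
    va <- a[i, ][!is.na(a[i, ])]
    vb <- b[i, ][!is.na(b[i, ])]
    if (length(va) < min_n || length(vb) < min_n ||
        (length(va) + length(vb)) < 4) {
      return(list(mean_a = if (length(va)) mean(va) else NA_real_,
                  mean_b = if (length(vb)) mean(vb) else NA_real_,
                  n_a = length(va), n_b = length(vb),
                  p_value = NA_real_, testable = FALSE))
    }
    p <- tryCatch(
      t.test(log(va), log(vb), var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
    list(mean_a = mean(va), mean_b = mean(vb),
         n_a = length(va), n_b = length(vb),
         p_value = p, testable = is.finite(p))
  })
  out <- cbind(out, rbindlist(res))
  out[, fold_change := pmax(mean_a / mean_b, mean_b / mean_a)]
  out[, direction := sign(mean_a - mean_b)]
  padj <- out$p_value
  if (p_adjust != "none") {
    padj[out$testable] <- p.adjust(out$p_value[out$testable],
                                   method = p_adjust)
  }
  out[, significant := ifelse(testable,
                              fold_change >= fc_threshold & padj <= alpha,
                              NA)]
  out[]
}
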