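# The multivariate model core: PCA with 7-fold cross-validated Q2, and an
# orthogonal projections to latent structures discriminant analysis
# (OPLS-DA) written from first principles in the Trygg & Wold (2002)
# formulation: a single predictive component whose weight is proportional
# to X'y, preceded by the iterative removal of components orthogonal to y.
# VIP scores, S-plot coordinates and a SIMCA-style permutation validation
# complete the stage.

# deterministic interleaved k-fold assignment, seeded from the sorted row
# ids so the folds are invariant to the order samples arrive in
.interleaved_folds <- function(ids, k) {
  n <- length(ids)
  if (k < 2 || k > n) stop("cv_folds must lie in [2, n samples]",
                           call. = FALSE)
  fold <- integer(n)
  fold[order(ids)] <- rep_len(seq_len(k), n)
  fold
}

.as_model_matrix <- function(x) {
  if (inherits(x, "scaled_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("x must be a numeric matrix or a scaled_matrix", call. = FALSE)
}

# class vector -> +1/-1 coding; first sorted level is +1
.encode_y <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) return(as.numeric(y))
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) {
    stop("y must have exactly two levels, found ", length(lev), call. = FALSE)
  }
  ifelse(as.character(y) == lev[1], 1, -1)
}

#' PCA with cross-validated Q2
#'
#' Principal components from the singular value decomposition of the
#' (already centered and scaled) matrix. Per-component explained variance
#' R2X_a is the component eigenvalue over the total sum of squares. Q2 is
#' estimated by row-wise k-fold cross-validation: held-out rows are
#' projected onto loadings fitted without them and the squared
#' reconstruction error accumulates into PRESS; Q2 = 1 - PRESS/SS.
#'
#' @param x A `scaled_matrix` (see [pareto_scale()]) or centered numeric
#'   matrix.
#' @param n_components Number of components; at most `min(n - 1, p)`.
#' @param cv_folds Folds for the Q2 estimate (default 7); folds are
#'   interleaved deterministically over the sorted sample ids.
#' @return An object of class `"pca_model"` with `scores`, `loadings`,
#'   `r2x_per_component`, `r2x_cum` and `q2_cum`.
#' @export
fit_pca <- function(x, n_components, cv_folds = 7) {
  X <- .as_model_matrix(x)
  n <- nrow(X)
  p <- ncol(X)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("n_components must lie in [1, min(n-1, p)]", call. = FALSE)
  }
  ss_tot <- sum(X^2)
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  r2x <- sv$d[seq_len(n_components)]^2 / ss_tot

  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row%06d", seq_len(n))
  fold <- .interleaved_folds(ids, cv_folds)
  press <- 0
  for (f in seq_len(cv_folds)) {
    test <- fold == f
    P <- svd(X[!test, , drop = FALSE], nu = 0, nv = n_components)$v
    resid <- X[test, , drop = FALSE] -
      X[test, , drop = FALSE] %*% P %*% t(P)
    press <- press + sum(resid^2)
  }
  structure(
    list(n_components = n_components, scores = scores, loadings = loadings,
         r2x_per_component = r2x, r2x_cum = sum(r2x),
         q2_cum = 1 - press / ss_tot, cv_folds = cv_folds),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d components, R2X(cum) = %.3f, Q2(cum) = %.3f (%d-fold CV)\n",
              x$n_components, x$r2x_cum, x$q2_cum, x$cv_folds))
  invisible(x)
}

# Core O-PLS fit on a centered X and centered y. Returns weights, scores and
# loadings of the orthogonal components plus the final 1-component
# predictive fit on the deflated matrix.
.opls_core <- function(X, yc, k_orth) {
  w <- crossprod(X, yc)
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) {
    stop("X carries no covariance with y; cannot fit", call. = FALSE)
  }
  w <- w / nw
  p_feat <- ncol(X)
  W_o <- P_o <- matrix(0, p_feat, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- X
  for (j in seq_len(k_orth)) {
    t_j <- Xd %*% w
    p_j <- crossprod(Xd, t_j) / sum(t_j^2)
    w_o <- p_j - as.numeric(crossprod(w, p_j)) * w
    n_o <- sqrt(sum(w_o^2))
    if (n_o < 1e-12) break   # no orthogonal variation left
    w_o <- w_o / n_o
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  t_pred <- Xd %*% w
  p_pred <- crossprod(Xd, t_pred) / sum(t_pred^2)
  c_coef <- sum(yc * t_pred) / sum(t_pred^2)
  list(w = w, t_pred = t_pred, p_pred = p_pred, c_coef = c_coef,
       W_o = W_o, P_o = P_o, T_o = T_o, X_deflated = Xd)
}

# Predict centered-y for new rows given a fitted core: remove the orthogonal
# components with the training weights/loadings, then score.
.opls_predict <- function(core, Xnew) {
  Xd <- Xnew
  k <- ncol(core$W_o)
  for (j in seq_len(k)) {
    t_o <- Xd %*% core$W_o[, j]
    Xd <- Xd - t_o %*% t(core$P_o[, j])
  }
  drop(Xd %*% core$w) * core$c_coef
}

.opls_q2 <- function(X, yc, k_orth, cv_folds) {
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row%06d", seq_len(nrow(X)))
  fold <- .interleaved_folds(ids, cv_folds)
  press <- 0
  for (f in seq_len(cv_folds)) {
    test <- fold == f
    core <- .opls_core(X[!test, , drop = FALSE], yc[!test], k_orth)
    pred <- .opls_predict(core, X[test, , drop = FALSE])
    press <- press + sum((yc[test] - pred)^2)
  }
  1 - press / sum(yc^2)
}

#' Fit an OPLS-DA model
#'
#' One predictive and `k_orth` orthogonal components in the Trygg & Wold
#' O-PLS formulation. The class vector is coded +1/-1 internally (first
#' sorted level is +1) and centered; X must already be scaled (typically
#' Pareto). With `k_orth = 0` the model is exactly a 1-component PLS-DA.
#' `k_orth = "auto"` keeps adding orthogonal components while the
#' cross-validated Q2 improves by more than 0.01, the SIMCA-like rule.
#'
#' @param x A `scaled_matrix` or centered numeric matrix (samples x
#'   features).
#' @param y Two-level class vector (factor, character, or +1/-1 numeric).
#' @param k_orth Number of orthogonal components, or `"auto"`.
#' @param cv_folds Folds for Q2 (default 7), interleaved over sorted sample
#'   ids.
#' @return An object of class `"oplsda_model"`: predictive scores/loadings/
#'   weights (`t_pred`, `p_pred`, `w_pred`), orthogonal blocks (`t_orth`,
#'   `p_orth`, `w_orth`, `k_orth`), `r2x_cum`, `r2y_cum`, `q2_cum`, the
#'   per-feature `vip`, and `s_plot` coordinates (covariance `p1` and
#'   correlation `pcorr1` of each feature with the predictive score).
#' @export
fit_oplsda <- function(x, y, k_orth = "auto", cv_folds = 7) {
  X <- .as_model_matrix(x)
  n <- nrow(X)
  yy <- .encode_y(y)
  if (length(yy) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  yc <- yy - mean(yy)
  if (all(yc == 0)) stop("y has a single class", call. = FALSE)

  max_k <- n - 3   # keep k_orth < n - 2
  if (identical(k_orth, "auto")) {
    q2_prev <- .opls_q2(X, yc, 0L, cv_folds)
    k_sel <- 0L
    while (k_sel < max_k) {
      q2_next <- .opls_q2(X, yc, k_sel + 1L, cv_folds)
      if (q2_next - q2_prev > 0.01) {
        k_sel <- k_sel + 1L
        q2_prev <- q2_next
      } else break
    }
    k_orth <- k_sel
  } else {
    k_orth <- as.integer(k_orth)
    if (k_orth < 0 || k_orth >= n - 2) {
      stop("k_orth must lie in [0, n - 3]", call. = FALSE)
    }
  }

  core <- .opls_core(X, yc, k_orth)
  k_orth <- ncol(core$W_o)   # may be fewer if variation ran out
  yhat <- drop(core$t_pred) * core$c_coef
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)

  ss_tot <- sum(X^2)
  ss_pred <- sum(core$t_pred^2) * sum(core$p_pred^2)
  ss_orth <- if (k_orth > 0) {
    sum(vapply(seq_len(k_orth), function(j)
      sum(core$T_o[, j]^2) * sum(core$P_o[, j]^2), numeric(1)))
  } else 0
  r2x <- (ss_pred + ss_orth) / ss_tot

  q2 <- .opls_q2(X, yc, k_orth, cv_folds)
  vip <- .opls_vip(core, yc)
  t1 <- drop(core$t_pred)
  s_plot <- data.frame(
    feature_id = colnames(X),
    p1 = as.numeric(stats::cov(t1, X)),
    pcorr1 = as.numeric(suppressWarnings(stats::cor(t1, X))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  s_plot$pcorr1[is.na(s_plot$pcorr1)] <- 0   # constant feature columns

  structure(
    list(t_pred = t1, p_pred = drop(core$p_pred), w_pred = drop(core$w),
         c_coef = core$c_coef,
         t_orth = core$T_o, p_orth = core$P_o, w_orth = core$W_o,
         k_orth = k_orth, r2x_cum = r2x, r2y_cum = r2y, q2_cum = q2,
         vip = stats::setNames(vip, colnames(X)), s_plot = s_plot,
         cv_folds = cv_folds, y_levels = sort(unique(as.character(y)))),
    class = "oplsda_model"
  )
}

# VIP over predictive + orthogonal components, weighted by the sum of
# squares of y explained by each component's score (the "VIP total"
# convention); orthogonal components explain essentially none of y, so their
# weight collapses numerically and the mean of VIP^2 over features is 1 by
# construction.
.opls_vip <- function(core, yc) {
  W <- cbind(core$w, core$W_o)
  Tm <- cbind(core$t_pred, core$T_o)
  p <- nrow(W)
  ssy <- vapply(seq_len(ncol(Tm)), function(a) {
    t_a <- Tm[, a]
    sum(t_a * yc)^2 / sum(t_a^2)
  }, numeric(1))
  wn2 <- sweep(W^2, 2, colSums(W^2), `/`)   # (w_af / ||w_a||)^2
  sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: 1 predictive + %d orthogonal components\nR2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f (%d-fold CV)\n",
    x$k_orth, x$r2x_cum, x$r2y_cum, x$q2_cum, x$cv_folds))
  cat(sprintf("features with VIP > 1: %d of %d\n",
              sum(x$vip > 1), length(x$vip)))
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' @param model A fitted `oplsda_model`.
#' @return Named numeric vector of per-feature VIP scores; their squares
#'   average to 1 across features.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "oplsda_model"))
  model$vip
}

#' Select features with VIP above a threshold
#'
#' @param model A fitted `oplsda_model`.
#' @param threshold VIP cutoff (default 1, the customary rule).
#' @return Character vector of feature ids with VIP strictly above the
#'   threshold.
#' @export
select_vip <- function(model, threshold = 1) {
  v <- vip_scores(model)
  names(v)[v > threshold]
}

#' SIMCA-style permutation validation of an OPLS-DA model
#'
#' Refits the model with identical hyperparameters on class labels shuffled
#' `n_perm` times, recording R2Y, Q2 and the absolute correlation of each
#' permuted label vector with the original. The regression lines through
#' the (correlation, statistic) pairs — including the unpermuted model at
#' correlation 1 — give the R2 and Q2 intercepts at correlation 0; strongly
#' negative Q2 intercepts indicate the original model is not an overfitting
#' artefact.
#'
#' @param x A `scaled_matrix` or centered matrix.
#' @param y Two-level class vector.
#' @param k_orth Number of orthogonal components (fixed; no auto here so
#'   every refit uses the original model's complexity).
#' @param cv_folds CV folds for Q2.
#' @param n_perm Number of permutations (default 200, minimum 20).
#' @param seed Integer seed for the label shuffles.
#' @return An object of class `"oplsda_permutation"`: `r2_perm`, `q2_perm`,
#'   `y_correlations`, the original `r2_orig`/`q2_orig`, the intercepts
#'   `r2_intercept`/`q2_intercept`, and the empirical p-value of the
#'   original Q2 against the permuted ones.
#' @export
permutation_test <- function(x, y, k_orth, cv_folds = 7, n_perm = 200,
                             seed = 1L) {
  if (n_perm < 20) stop("n_perm must be at least 20", call. = FALSE)
  X <- .as_model_matrix(x)
  yy <- .encode_y(y)
  orig <- fit_oplsda(X, yy, k_orth = k_orth, cv_folds = cv_folds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  r2p <- q2p <- ycor <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- yy[sample.int(length(yy))]
    m <- fit_oplsda(X, yp, k_orth = k_orth, cv_folds = cv_folds)
    r2p[i] <- m$r2y_cum
    q2p[i] <- m$q2_cum
    ycor[i] <- abs(stats::cor(yp, yy))
  }
  fit_int <- function(stat, stat0) {
    unname(stats::coef(stats::lm(c(stat, stat0) ~ c(ycor, 1)))[1])
  }
  structure(
    list(n_permutations = n_perm, r2_perm = r2p, q2_perm = q2p,
         y_correlations = ycor,
         r2_orig = orig$r2y_cum, q2_orig = orig$q2_cum,
         r2_intercept = fit_int(r2p, orig$r2y_cum),
         q2_intercept = fit_int(q2p, orig$q2_cum),
         p_value = (1 + sum(q2p >= orig$q2_cum)) / (1 + n_perm)),
    class = "oplsda_permutation"
  )
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (n = %d): R2 intercept = %.3f, Q2 intercept = %.3f\noriginal Q2 = %.3f, empirical p = %.4f\n",
    x$n_permutations, x$r2_intercept, x$q2_intercept, x$q2_orig, x$p_value))
  invisible(x)
}
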