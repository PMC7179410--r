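test_that("PCA explained variance is exact on low-rank matrices", {
  set.seed(1)
  base <- rnorm(6)
  X <- outer(c(3, -1, 2, -4), base)          # rank 1
  X <- scale(X, center = TRUE, scale = FALSE)
  rownames(X) <- sprintf("s%d", 1:4)
  colnames(X) <- sprintf("f%d", 1:6)
  m <- fit_pca(X, n_components = 1, cv_folds = 2)
  expect_equal(m$r2x_per_component[1], 1.0, tolerance = 1e-12)

  set.seed(2)
  X2 <- matrix(rnorm(5 * 4), 5, 4)
  X2 <- scale(X2, center = TRUE, scale = FALSE)
  dimnames(X2) <- list(sprintf("s%d", 1:5), sprintf("f%d", 1:4))
  m2 <- fit_pca(X2, n_components = 4, cv_folds = 2)   # full rank after centering
  expect_equal(m2$r2x_cum, 1.0, tolerance = 1e-10)
  expect_true(all(diff(cumsum(m2$r2x_per_component)) >= -1e-12))
  # loadings orthonormal
  G <- crossprod(m2$loadings)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA Q2 equals an explicit brute-force PRESS loop", {
  sm <- make_signal_matrix(n_a = 15, n_b = 12, p = 20, seed = 7)
  X <- sm$x
  k <- 7
  a <- 3
  m <- fit_pca(X, n_components = a, cv_folds = k)
  # independent oracle: assign interleaved folds over sorted row names,
  # refit on the complement, project held-out rows, accumulate PRESS
  fold <- integer(nrow(X))
  fold[order(rownames(X))] <- rep_len(1:k, nrow(X))
  press <- 0
  for (f in 1:k) {
    tr <- X[fold != f, , drop = FALSE]
    te <- X[fold == f, , drop = FALSE]
    P <- svd(tr)$v[, 1:a, drop = FALSE]
    press <- press + sum((te - te %*% P %*% t(P))^2)
  }
  expect_equal(m$q2_cum, 1 - press / sum(X^2), tolerance = 1e-10)
  expect_lte(m$q2_cum, m$r2x_cum)
})

test_that("PCA rejects infeasible component counts", {
  sm <- make_signal_matrix(n_a = 5, n_b = 5, p = 6)
  expect_error(fit_pca(sm$x, n_components = 10), "n_components")
})

test_that("a perfect predictor dominates the OPLS-DA model", {
  set.seed(3)
  n <- 24
  y <- rep(c("ga", "gb"), each = n / 2)
  X <- cbind(perfect = ifelse(y == "ga", 1, -1),
             matrix(rnorm(n * 9), n, 9))
  colnames(X)[2:10] <- sprintf("noise%d", 1:9)
  rownames(X) <- sprintf("s%02d", 1:n)
  X <- scale(X, center = TRUE, scale = FALSE)
  m <- fit_oplsda(X, y, k_orth = "auto")
  expect_gte(m$r2y_cum, 0.99)
  expect_equal(names(which.max(m$vip)), "perfect")
})

test_that("VIP satisfies its normalization identity and the 2-feature toy", {
  # toy: feature 1 equals y, feature 2 pure noise -> w ~ (1, ~0),
  # VIP ~ (sqrt(2), ~0) by direct evaluation of the formula
  set.seed(4)
  y <- rep(c(1, -1), each = 10)
  X <- cbind(f1 = y, f2 = rnorm(20))
  X <- scale(X, center = TRUE, scale = FALSE)
  rownames(X) <- sprintf("s%02d", 1:20)
  m <- fit_oplsda(X, y, k_orth = 0)
  expect_equal(unname(m$vip["f1"]), sqrt(2), tolerance = 0.05)
  expect_lt(unname(m$vip["f2"]), 0.35)

  # identity on a generic fitted model: mean(VIP^2) = 1
  sm <- make_signal_matrix(seed = 9)
  m2 <- fit_oplsda(sm$x, sm$y, k_orth = 2)
  expect_equal(mean(m2$vip^2), 1, tolerance = 1e-6)

  # all features identical -> all VIPs 1
  Xi <- matrix(rep(scale(rnorm(20), scale = FALSE), 5), 20, 5)
  dimnames(Xi) <- list(sprintf("s%02d", 1:20), sprintf("f%d", 1:5))
  yi <- rep(c("a", "b"), 10)
  mi <- fit_oplsda(Xi, yi, k_orth = 0)
  expect_equal(unname(mi$vip), rep(1, 5), tolerance = 1e-8)
})

test_that("predictive score is orthogonal to every orthogonal score", {
  sm <- make_signal_matrix(seed = 10)
  m <- fit_oplsda(sm$x, sm$y, k_orth = 3)
  expect_equal(m$k_orth, 3)
  for (j in seq_len(m$k_orth)) {
    ip <- abs(sum(m$t_pred * m$t_orth[, j]))
    expect_lt(ip, 1e-8 * sqrt(sum(m$t_pred^2) * sum(m$t_orth[, j]^2)))
  }
  # S-plot correlations are bona fide correlations
  expect_true(all(m$s_plot$pcorr1 >= -1 & m$s_plot$pcorr1 <= 1))
})

test_that("deflation conserves the total variance of X", {
  sm <- make_signal_matrix(seed = 11)
  m <- fit_oplsda(sm$x, sm$y, k_orth = 2)
  X <- sm$x
  recon_orth <- m$t_orth %*% t(m$p_orth)
  recon_pred <- m$t_pred %*% t(m$p_pred)
  E <- X - recon_orth - recon_pred
  ss_parts <- sum(recon_orth^2) + sum(recon_pred^2) + sum(E^2)
  expect_equal(ss_parts / sum(X^2), 1, tolerance = 1e-8)
  expect_equal(m$r2x_cum, (sum(recon_orth^2) + sum(recon_pred^2)) / sum(X^2),
               tolerance = 1e-8)
})

test_that("k_orth = 0 reproduces 1-component NIPALS PLS exactly", {
  sm <- make_signal_matrix(seed = 12)
  m <- fit_oplsda(sm$x, sm$y, k_orth = 0)
  oracle <- nipals_pls1(sm$x, ifelse(sm$y == "ga", 1, -1))
  expect_equal(abs(cor(m$t_pred, oracle$t)), 1, tolerance = 1e-10)
  expect_equal(abs(cor(m$w_pred, oracle$w)), 1, tolerance = 1e-10)
})

test_that("the predictive scores match an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  sm <- make_signal_matrix(seed = 13)
  m <- fit_oplsda(sm$x, sm$y, k_orth = 0)
  ref <- mixOmics::pls(sm$x, ifelse(sm$y == "ga", 1, -1), ncomp = 1,
                       scale = FALSE, mode = "regression")
  expect_equal(abs(cor(m$t_pred, ref$variates$X[, 1])), 1, tolerance = 1e-8)
})

test_that("removing a planted orthogonal component improves Q2", {
  set.seed(14)
  n <- 40
  p <- 30
  y <- rep(c(1, -1), each = n / 2)
  t_o <- rnorm(n)
  t_o <- t_o - mean(t_o)
  t_o <- t_o - y * sum(t_o * y) / sum(y * y)   # exactly y-orthogonal
  X <- outer(y, runif(p, 0, 0.6)) + outer(t_o, runif(p, 0.5, 1.5)) +
    matrix(rnorm(n * p, sd = 0.4), n, p)
  dimnames(X) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p))
  X <- scale(X, center = TRUE, scale = FALSE)
  m0 <- fit_oplsda(X, y, k_orth = 0)
  m1 <- fit_oplsda(X, y, k_orth = 1)
  expect_gte(m1$q2_cum, m0$q2_cum)
  expect_gte(abs(cor(m1$t_orth[, 1], t_o)), 0.8)
})

test_that("Q2 is invariant to the order samples arrive in", {
  sm <- make_signal_matrix(seed = 15)
  perm <- sample(nrow(sm$x))
  m1 <- fit_oplsda(sm$x, sm$y, k_orth = 1)
  m2 <- fit_oplsda(sm$x[perm, ], sm$y[perm], k_orth = 1)
  expect_equal(m1$q2_cum, m2$q2_cum, tolerance = 1e-10)
  p1 <- fit_pca(sm$x, 3)
  p2 <- fit_pca(sm$x[perm, ], 3)
  expect_equal(p1$q2_cum, p2$q2_cum, tolerance = 1e-10)
})

test_that("single-class y and infeasible k_orth are rejected", {
  sm <- make_signal_matrix(seed = 16)
  expect_error(fit_oplsda(sm$x, rep("ga", nrow(sm$x)), k_orth = 0),
               "two levels")
  expect_error(fit_oplsda(sm$x, sm$y, k_orth = nrow(sm$x)), "k_orth")
})

test_that("permutation test flags informative models and reports intercepts", {
  sm <- make_signal_matrix(n_a = 15, n_b = 15, p = 30, delta = 1.5, seed = 17)
  perm <- permutation_test(sm$x, sm$y, k_orth = 1, n_perm = 50, seed = 1)
  expect_length(perm$q2_perm, 50)
  expect_true(all(perm$y_correlations >= 0 & perm$y_correlations <= 1))
  expect_gt(perm$q2_orig, max(perm$q2_perm))
  expect_lt(perm$p_value, 0.05)
  # the original statistics equal an identically-parameterized refit
  m <- fit_oplsda(sm$x, sm$y, k_orth = 1)
  expect_equal(perm$r2_orig, m$r2y_cum, tolerance = 1e-12)
  expect_equal(perm$q2_orig, m$q2_cum, tolerance = 1e-12)
  # determinism under the same seed
  perm2 <- permutation_test(sm$x, sm$y, k_orth = 1, n_perm = 50, seed = 1)
  expect_identical(perm$q2_perm, perm2$q2_perm)
})

test_that("on pure noise the Q2 intercept sits near the original Q2", {
  # overfit-flagging behavior: with no signal, permuted and original models
  # are statistically exchangeable, so the intercept tracks the original
  diffs <- sapply(1:10, function(s) {
    set.seed(300 + s)
    n <- 40
    X <- matrix(rnorm(n * 50), n, 50)
    dimnames(X) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:50))
    X <- scale(X, center = TRUE, scale = FALSE)
    y <- rep(c("a", "b"), each = n / 2)
    p <- permutation_test(X, y, k_orth = 0, n_perm = 50, seed = s)
    p$q2_intercept - p$q2_orig
  })
  expect_lt(median(abs(diffs)), 0.2)
})
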