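make_rf_data <- function(n = 40, p = 6, seed = 50, perfect = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
  for (j in seq_len(perfect)) X[y == "a", j] <- X[y == "a", j] + 6
  list(x = X, y = y)
}

test_that("rankings are permutations and reproducible from the base seed", {
  d <- make_rf_data()
  log1 <- iterate_rf_importance(d$x, d$y, n_iterations = 10, n_trees = 100,
                                seed = 7)
  log2 <- iterate_rf_importance(d$x, d$y, n_iterations = 10, n_trees = 100,
                                seed = 7)
  expect_identical(log1$rankings, log2$rankings)
  for (i in seq_len(nrow(log1$rankings))) {
    expect_setequal(log1$rankings[i, ], seq_len(ncol(d$x)))
  }
  expect_equal(log1$mtry, floor(sqrt(ncol(d$x))))
  # a different base seed changes at least something
  log3 <- iterate_rf_importance(d$x, d$y, n_iterations = 10, n_trees = 100,
                                seed = 8)
  expect_false(identical(log1$rankings, log3$rankings))
})

test_that("a single perfect predictor is rank 1 nearly always", {
  d <- make_rf_data(p = 2, perfect = 1)
  log <- iterate_rf_importance(d$x, d$y, n_iterations = 100, n_trees = 200,
                               seed = 1)
  expect_gte(sum(log$rankings[, "F01"] == 1), 95)
  expect_error(iterate_rf_importance(d$x[, 1, drop = FALSE], d$y),
               "at least 2 features")
})

test_that("cumulative top-N matrix obeys its counting identities", {
  d <- make_rf_data(p = 8, perfect = 2)
  log <- iterate_rf_importance(d$x, d$y, n_iterations = 20, n_trees = 100,
                               seed = 3)
  cm <- cumulative_topN(log)
  p <- ncol(d$x)
  expect_equal(unname(cm[, p]), rep(20L, p))          # whole-range identity
  expect_true(all(apply(cm, 1, function(r) all(diff(r) >= 0))))
  # top-1 frequencies sum to the number of iterations
  expect_equal(sum(top1_frequency(log)), 20L)
})

test_that("strong planted markers enter the stable set among 47 features", {
  # 10 strong discriminant features among 47, mirroring the VIP-set size the
  # selection stage typically receives
  set.seed(60)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 47), n, 47,
              dimnames = list(NULL, sprintf("F%02d", 1:47)))
  markers <- sprintf("F%02d", 1:10)
  X[y == "a", 1:10] <- X[y == "a", 1:10] + 2.5
  log <- iterate_rf_importance(X, y, n_iterations = 30, n_trees = 300,
                               seed = 2)
  ss35 <- stable_set(log, n_star = 35)
  expect_true(all(markers %in% ss35))
  # the automatic rule finds a plateau containing every marker
  ss_auto <- stable_set(log, n_star = "auto")
  expect_true(all(markers %in% ss_auto))
})

test_that("top1_select applies an inclusive frequency threshold", {
  freq <- setNames(c(9, 6, 5, 5, 5, 5, 4, 4, 4, 4, 4, rep(0, 36)),
                   sprintf("V%02d", 1:47))
  expect_length(top1_select(freq, min_frequency = 4), 11)
  expect_length(top1_select(freq, min_frequency = 5), 6)
  expect_length(top1_select(freq, min_frequency = 1), 11)
})

test_that("final forest on separable groups reaches OOB 0 and AUC 1", {
  sim <- synthesize_table(synthetic_config(seed = 70, log2_fold_change = 4,
                                           biological_cv = 0.1))
  tab <- impute_half_min(subset_features(
    sim$table, samples = sim$table$sample_ids[sim$table$groups != "qc"]))
  x <- tab$abundances[, sim$truth$marker_feature_ids]
  ev <- final_model_eval(x, tab$groups, seed = 5)
  expect_equal(ev$oob_error, 0)
  expect_equal(ev$auc, 1.0)
  # a single perfectly predictive marker also gives AUC 1
  d <- make_rf_data(p = 2, perfect = 1)
  ev1 <- final_model_eval(d$x[, 1, drop = FALSE], d$y, n_trees = 200,
                          seed = 1)
  expect_equal(ev1$auc, 1.0)
})

test_that("permuted labels give chance-level AUC", {
  sim <- synthesize_table(synthetic_config(seed = 71))
  tab <- impute_half_min(subset_features(
    sim$table, samples = sim$table$sample_ids[sim$table$groups != "qc"]))
  x <- tab$abundances[, sim$truth$marker_feature_ids]
  aucs <- sapply(1:10, function(s) {
    set.seed(500 + s)
    yperm <- sample(tab$groups)
    final_model_eval(x, yperm, n_trees = 200, seed = s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})
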