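# Iterative random-forest refinement of the VIP-selected features: 100
# forests with distinct seeds, per-iteration permutation-importance
# rankings, a cumulative top-N matrix, rank-1 frequencies as the selection
# statistic, and a final forest on the selected markers evaluated by OOB
# error and OOB-vote ROC AUC.

#' Rank features by permutation importance over repeated forests
#'
#' Fits `n_iterations` random forests, each with its own seed
#' (`seed + i`), and records the per-iteration importance ranking
#' (1 = most important). Importance is the permutation (mean decrease in
#' accuracy) measure by default; ties are broken by ascending feature
#' position so the ranking is deterministic.
#'
#' @param x Numeric matrix (samples x features), typically restricted to
#'   the VIP-selected features; at least 2 features.
#' @param y Two-level class vector.
#' @param n_iterations Number of forest fits (default 100).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Candidate features per split; default
#'   `floor(sqrt(ncol(x)))`, the classification default.
#' @param seed Base seed; iteration i uses `seed + i`.
#' @param importance `"permutation"` (mean decrease accuracy, default) or
#'   `"gini"` (mean decrease in node impurity).
#' @return An object of class `"rf_iteration_log"`: `rankings`
#'   (iterations x features, each row a permutation of 1..p), `seeds`,
#'   and the fitting parameters.
#' @export
iterate_rf_importance <- function(x, y, n_iterations = 100, n_trees = 500,
                                  mtry = NULL, seed = 1L,
                                  importance = c("permutation", "gini")) {
  stopifnot(is.matrix(x), is.numeric(x))
  importance <- match.arg(importance)
  p <- ncol(x)
  if (p < 2) stop("ranking needs at least 2 features", call. = FALSE)
  yf <- factor(y)
  if (nlevels(yf) != 2 || any(table(yf) == 0)) {
    stop("y must contain both classes", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%03d", seq_len(p))
  type <- if (importance == "permutation") 1 else 2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  seeds <- seed + seq_len(n_iterations)
  rankings <- matrix(0L, n_iterations, p,
                     dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n_iterations)) {
    set.seed(seeds[i])
    rf <- randomForest::randomForest(x, yf, ntree = n_trees, mtry = mtry,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = type)[, 1]
    ord <- order(-imp, seq_len(p))
    rankings[i, ord] <- seq_len(p)
  }
  structure(
    list(rankings = rankings, seeds = seeds, n_iterations = n_iterations,
         n_trees = n_trees, mtry = mtry, importance = importance,
         feature_ids = colnames(x)),
    class = "rf_iteration_log"
  )
}

#' Cumulative top-N matrix of importance rankings
#'
#' `C[v, N]` counts the iterations in which feature v ranked within the top
#' N. Features whose count reaches the number of iterations at a moderate N
#' form the stable set.
#'
#' @param log An `rf_iteration_log`.
#' @return Integer matrix (features x N), non-decreasing along N with
#'   `C[v, p] = n_iterations` for every feature.
#' @export
cumulative_topN <- function(log) {
  stopifnot(inherits(log, "rf_iteration_log"))
  r <- log$rankings
  p <- ncol(r)
  out <- vapply(seq_len(p), function(N) as.integer(colSums(r <= N)),
                integer(p))
  dimnames(out) <- list(log$feature_ids, seq_len(p))
  out
}

#' Stable feature set at a top-N threshold
#'
#' Features ranked within the top `n_star` in every single iteration. With
#' `n_star = "auto"`, the smallest N whose stable-set size is unchanged for
#' 3 consecutive values of N is used.
#'
#' @param log An `rf_iteration_log`.
#' @param n_star Top-N threshold (integer) or `"auto"`.
#' @return Character vector of stable feature ids.
#' @export
stable_set <- function(log, n_star = "auto") {
  cm <- cumulative_topN(log)
  p <- ncol(cm)
  if (identical(n_star, "auto")) {
    sizes <- vapply(seq_len(p), function(N)
      sum(cm[, N] == log$n_iterations), integer(1))
    # first non-empty plateau: the trivial empty set at small N is skipped
    n_star <- p
    for (N in seq_len(p - 2)) {
      if (sizes[N] > 0 && sizes[N] == sizes[N + 1] &&
          sizes[N] == sizes[N + 2]) {
        n_star <- N
        break
      }
    }
  } else {
    n_star <- as.integer(n_star)
    stopifnot(n_star >= 1, n_star <= p)
  }
  rownames(cm)[cm[, n_star] == log$n_iterations]
}

#' Rank-1 frequency of each feature
#'
#' @param log An `rf_iteration_log`.
#' @return Named integer vector: how often each feature was the single most
#'   important one; sums to the number of iterations.
#' @export
top1_frequency <- function(log) {
  stopifnot(inherits(log, "rf_iteration_log"))
  colSums(log$rankings == 1L)
}

#' Select markers by rank-1 frequency
#'
#' Features that were the most important variable in at least
#' `min_frequency` iterations. The boundary is inclusive: a feature
#' reaching the threshold exactly is selected.
#'
#' @param log An `rf_iteration_log`, or a named numeric vector of rank-1
#'   frequencies.
#' @param min_frequency Minimum rank-1 count (default 4).
#' @return Character vector of selected feature ids (names of the frequency
#'   vector).
#' @export
top1_select <- function(log, min_frequency = 4) {
  freq <- if (inherits(log, "rf_iteration_log")) top1_frequency(log)
          else log
  stopifnot(is.numeric(freq), !is.null(names(freq)))
  names(freq)[freq >= min_frequency]
}

#' Evaluate a final forest on the selected markers
#'
#' Fits one random forest on the selected features and reports the
#' out-of-bag error rate and the ROC AUC computed from the OOB class-vote
#' fractions against the true labels (no separate test split; the OOB
#' mechanism provides the held-out predictions).
#'
#' @param x Numeric matrix restricted to the selected markers (>= 1
#'   column).
#' @param y Two-level class vector.
#' @param n_trees Trees (default 500).
#' @param seed Seed for the forest.
#' @return A list with `oob_error`, `auc` and the fitted `forest`.
#' @export
final_model_eval <- function(x, y, n_trees = 500, seed = 1L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 1) stop("no markers selected; nothing to evaluate",
                        call. = FALSE)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two levels", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rf <- randomForest::randomForest(x, yf, ntree = n_trees)
  oob <- unname(rf$err.rate[n_trees, "OOB"])
  votes <- rf$votes[, levels(yf)[2]]
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = yf, predictor = votes, levels = levels(yf),
    direction = "<", quiet = TRUE)))
  list(oob_error = oob, auc = auc, forest = rf)
}
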