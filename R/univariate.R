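# Per-feature two-group screening with Student's t (pooled variance), and
# the z-scored, hierarchically clustered matrix behind the usual
# significant-feature heat map.

#' Per-feature two-sample t-test screen
#'
#' Runs a two-sided pooled-variance Student's t-test on every feature
#' between the two biological groups (QC samples excluded), on imputed raw
#' abundances by default — scaling belongs to the multivariate stage, not
#' here. Features whose pooled variance is zero (both groups constant and
#' equal) get t = 0, p = 1 with a warning. No multiple-testing correction is
#' applied by default, matching the conventional raw p < alpha screen;
#' Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param table A `feature_table`; both groups need >= 2 samples.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param log2_transform If `TRUE`, test log2(imputed abundances) instead of
#'   the raw scale.
#' @param welch If `TRUE`, use the Welch (unequal-variance) test instead of
#'   the pooled-variance Student's t.
#' @param adjust `"none"` (default) or `"BH"`; the `significant` flag is set
#'   on the (possibly adjusted) p-value.
#' @return A data.frame with one row per feature: `feature_id`,
#'   `t_statistic`, `p_value`, `log2_fold_change` (group_a over group_b) and
#'   `significant`.
#' @export
t_test_screen <- function(table, alpha = 0.05, log2_transform = FALSE,
                          welch = FALSE, adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"))
  adjust <- match.arg(adjust)
  a <- table$groups == "group_a"
  b <- table$groups == "group_b"
  if (sum(a) < 2 || sum(b) < 2) {
    stop("each biological group needs at least 2 samples", call. = FALSE)
  }
  x <- impute_half_min(table)$abundances
  if (log2_transform) {
    x <- log2(pmax(x, .Machine$double.xmin))
  }
  p <- ncol(x)
  tstat <- numeric(p)
  pval <- numeric(p)
  degenerate <- logical(p)
  for (j in seq_len(p)) {
    xa <- x[a, j]
    xb <- x[b, j]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      tstat[j] <- 0
      pval[j] <- 1
      degenerate[j] <- TRUE
      next
    }
    ht <- stats::t.test(xa, xb, var.equal = !welch,
                        alternative = "two.sided")
    tstat[j] <- unname(ht$statistic)
    pval[j] <- ht$p.value
  }
  if (any(degenerate)) {
    warning(sum(degenerate),
            " feature(s) with zero pooled variance; p set to 1")
  }
  if (adjust == "BH") pval <- stats::p.adjust(pval, method = "BH")
  ma <- colMeans(x[a, , drop = FALSE])
  mb <- colMeans(x[b, , drop = FALSE])
  lfc <- if (log2_transform) ma - mb else log2(ma / mb)
  data.frame(
    feature_id = table$feature_ids,
    t_statistic = tstat,
    p_value = pval,
    log2_fold_change = lfc,
    significant = pval < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Clustered z-score matrix of significant features
#'
#' Restricts the table to the significant features, z-scores each feature
#' across the non-QC samples, and orders rows (features) and columns
#' (samples) by average-linkage hierarchical clustering on Euclidean
#' distance — the matrix a heat map renderer would draw.
#'
#' @param table A `feature_table`.
#' @param results Output of [t_test_screen()] on the same table.
#' @return A list with `z_values` (significant features x biological
#'   samples), `row_order`, `col_order` (permutations), and the two
#'   `hclust` objects.
#' @export
heatmap_matrix <- function(table, results) {
  stopifnot(inherits(table, "feature_table"), is.data.frame(results))
  sig <- results$feature_id[results$significant]
  if (length(sig) < 2) {
    stop("need at least 2 significant features to cluster", call. = FALSE)
  }
  bio <- table$sample_ids[table$groups != "qc"]
  x <- impute_half_min(subset_features(table, sig, bio))$abundances
  z <- t(scale(x))          # features as rows, z-scored per feature
  z[is.nan(z)] <- 0         # constant features: flat row
  hr <- stats::hclust(stats::dist(z), method = "average")
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  list(z_values = z, row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
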