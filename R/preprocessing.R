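# Feature filtering and scaling applied before any modeling: first the
# QC-RSD stability filter, then the 80% presence rule, then (for the
# multivariate stages only) Pareto scaling. Missing cells are imputed with
# half the feature's minimum observed positive value, the usual
# below-detection convention in metabolomics.

#' Impute missing abundances with half the feature minimum
#'
#' Each `NA` cell is replaced by half of the smallest observed positive
#' value of that feature. Features with no positive observation at all have
#' their missing cells set to 0.
#'
#' @param table A `feature_table`.
#' @return A `feature_table` without missing cells.
#' @export
impute_half_min <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$abundances
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    pos <- x[!miss, j]
    pos <- pos[pos > 0]
    x[miss, j] <- if (length(pos)) min(pos) / 2 else 0
  }
  feature_table(x, table$groups, table$feature_mz, table$feature_rt)
}

.new_filter_report <- function(rule, n_input, removed_ids) {
  list(rule = rule, n_input = n_input, n_removed = length(removed_ids),
       n_retained = n_input - length(removed_ids), removed_ids = removed_ids)
}

#' Remove features unstable across QC injections
#'
#' The relative standard deviation (RSD, percent) of each feature over the
#' QC samples gauges analytical stability; features with RSD above the
#' threshold are removed, as are features whose QC mean is zero (RSD
#' undefined, treated as unstable). Missing QC cells are imputed with half
#' the feature's minimum observed value first. The n-1 standard deviation is
#' used, appropriate for small QC counts.
#'
#' @param table A `feature_table` with at least 2 QC samples.
#' @param threshold_pct RSD threshold in percent (default 15).
#' @return A list with the filtered `table` and a `report`.
#' @export
qc_rsd_filter <- function(table, threshold_pct = 15) {
  stopifnot(inherits(table, "feature_table"))
  if (sum(table$groups == "qc") < 2) {
    stop("QC-RSD filter needs at least 2 QC samples", call. = FALSE)
  }
  qc <- impute_half_min(table)$abundances[table$groups == "qc", , drop = FALSE]
  m <- colMeans(qc)
  s <- apply(qc, 2, stats::sd)
  rsd <- ifelse(m > 0, 100 * s / m, Inf)
  removed <- table$feature_ids[rsd > threshold_pct]
  kept <- setdiff(table$feature_ids, removed)
  list(
    table = subset_features(table, kept),
    report = .new_filter_report("qc_rsd", ncol(table$abundances), removed),
    rsd = stats::setNames(rsd, table$feature_ids)
  )
}

#' Apply the 80% presence rule
#'
#' A feature is retained iff it is present (non-missing and > 0) in at
#' least `threshold` of the samples of at least one biological group; the
#' boundary is inclusive and QC samples do not count.
#'
#' @param table A `feature_table` with both biological groups non-empty.
#' @param threshold Presence fraction required in one group (default 0.80).
#' @return A list with the filtered `table` and a `report`.
#' @export
eighty_percent_rule <- function(table, threshold = 0.80) {
  stopifnot(inherits(table, "feature_table"))
  a <- table$groups == "group_a"
  b <- table$groups == "group_b"
  if (!any(a) || !any(b)) {
    stop("both biological groups must be non-empty", call. = FALSE)
  }
  present <- !is.na(table$abundances) & table$abundances > 0
  frac_a <- colMeans(present[a, , drop = FALSE])
  frac_b <- colMeans(present[b, , drop = FALSE])
  keep <- frac_a >= threshold | frac_b >= threshold
  removed <- table$feature_ids[!keep]
  list(
    table = subset_features(table, table$feature_ids[keep]),
    report = .new_filter_report("eighty_percent", ncol(table$abundances),
                                removed)
  )
}

#' Run both feature filters in the standard order
#'
#' QC-RSD stability filter first, then the 80% presence rule on the
#' survivors; the combined report satisfies
#' `n_input - n_removed_qc_rsd - n_removed_80pct == n_retained` and the two
#' removal lists are disjoint.
#'
#' @param table A `feature_table`.
#' @param rsd_threshold_pct RSD threshold in percent (default 15).
#' @param presence_threshold Presence fraction (default 0.80).
#' @return A list with the filtered `table` and a combined `report`.
#' @export
filter_features <- function(table, rsd_threshold_pct = 15,
                            presence_threshold = 0.80) {
  step1 <- qc_rsd_filter(table, rsd_threshold_pct)
  step2 <- eighty_percent_rule(step1$table, presence_threshold)
  report <- list(
    n_input = ncol(table$abundances),
    n_removed_qc_rsd = step1$report$n_removed,
    n_removed_80pct = step2$report$n_removed,
    n_retained = ncol(step2$table$abundances),
    removed_ids = list(qc_rsd = step1$report$removed_ids,
                       eighty_percent = step2$report$removed_ids)
  )
  stopifnot(report$n_input - report$n_removed_qc_rsd -
              report$n_removed_80pct == report$n_retained)
  list(table = step2$table, report = report)
}

#' Pareto-scale a matrix
#'
#' Each column is mean-centered and divided by the square root of its n-1
#' standard deviation — the compromise between unit-variance scaling and no
#' scaling that is customary before PCA/OPLS-DA of LC-MS intensities.
#' Constant columns have no information and are dropped with a warning.
#'
#' @param x Numeric matrix (samples x features) without missing values.
#' @return An object of class `"scaled_matrix"`: list with `values`,
#'   `centers`, `scale_factors` (sqrt of sd) and `dropped` column names.
#' @export
pareto_scale <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x), nrow(x) >= 2)
  if (anyNA(x)) stop("missing values must be imputed before scaling",
                     call. = FALSE)
  centers <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (all(constant)) {
    stop("all columns are constant; nothing to scale", call. = FALSE)
  }
  if (any(constant)) {
    warning(sum(constant), " constant column(s) dropped before scaling")
  }
  keep <- which(!constant)
  sf <- sqrt(sds[keep])
  vals <- sweep(x[, keep, drop = FALSE], 2, centers[keep], `-`)
  vals <- sweep(vals, 2, sf, `/`)
  structure(
    list(values = vals, centers = centers[keep], scale_factors = sf,
         dropped = colnames(x)[constant]),
    class = "scaled_matrix"
  )
}
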