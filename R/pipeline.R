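# End-to-end orchestration: (synthesize or load) -> QC-RSD filter -> 80%
# rule -> t-test screen -> Pareto scaling -> OPLS-DA + VIP -> iterative RF
# importance -> top-1 frequency selection -> final forest evaluation.
# Defaults are the standard settings of this workflow (RSD 15%, presence
# 0.80, alpha 0.05, VIP > 1, 100 iterations x 500 trees, min frequency 4,
# 200 permutations, 7-fold CV).

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()], used when no input files are
#'   given.
#' @param input_path,metadata_path Optional paths to a feature-table CSV and
#'   its sample metadata; when supplied they take precedence over the
#'   synthetic generator.
#' @param rsd_threshold_pct QC-RSD filter threshold, percent.
#' @param presence_threshold 80%-rule presence fraction.
#' @param alpha t-test significance level.
#' @param vip_threshold VIP selection cutoff.
#' @param k_orth Orthogonal components for OPLS-DA, or `"auto"`.
#' @param cv_folds Cross-validation folds.
#' @param n_permutations Label permutations for model validation (0 skips
#'   the permutation test).
#' @param rf_iterations,rf_trees Random-forest iteration and tree counts.
#' @param min_frequency Rank-1 frequency cutoff for marker selection.
#' @param seed Global seed driving every stochastic stage.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_path = NULL, metadata_path = NULL,
                            rsd_threshold_pct = 15,
                            presence_threshold = 0.80,
                            alpha = 0.05, vip_threshold = 1.0,
                            k_orth = "auto", cv_folds = 7,
                            n_permutations = 200,
                            rf_iterations = 100, rf_trees = 500,
                            min_frequency = 4, seed = 1L) {
  stopifnot(rsd_threshold_pct > 0,
            presence_threshold > 0, presence_threshold <= 1,
            alpha > 0, alpha < 1, vip_threshold >= 0,
            cv_folds >= 2, rf_iterations >= 1, rf_trees >= 1,
            min_frequency >= 1)
  structure(
    list(synthetic = synthetic, input_path = input_path,
         metadata_path = metadata_path,
         rsd_threshold_pct = rsd_threshold_pct,
         presence_threshold = presence_threshold, alpha = alpha,
         vip_threshold = vip_threshold, k_orth = k_orth,
         cv_folds = cv_folds, n_permutations = n_permutations,
         rf_iterations = rf_iterations, rf_trees = rf_trees,
         min_frequency = min_frequency, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the marker-screening pipeline
#'
#' Executes every stage in order on either a loaded feature table or a
#' synthetic one, and returns a run report with all stage counts, the
#' model statistics, and the selected markers. Identical config and seed
#' give an identical report.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, intermediates (filter
#'   report, univariate results, VIP table, selection summary, report
#'   JSON) are written there as CSV/JSON.
#' @return A `"pipeline_report"` list: `counts` (n_input, n_retained,
#'   n_significant, n_vip, n_selected), `models` (PCA/OPLS-DA/permutation
#'   summaries), `selected_markers`, `final_oob_error`, `final_auc`, and
#'   `truth_recovery` when the run was synthetic.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic_run <- is.null(config$input_path)
  if (synthetic_run) {
    sim <- synthesize_table(config$synthetic)
    table <- sim$table
    truth <- sim$truth
  } else {
    table <- read_feature_table(config$input_path, config$metadata_path)
    truth <- NULL
  }

  filt <- filter_features(table, config$rsd_threshold_pct,
                          config$presence_threshold)
  uni <- t_test_screen(filt$table, alpha = config$alpha)

  bio_ids <- filt$table$sample_ids[filt$table$groups != "qc"]
  bio <- impute_half_min(subset_features(filt$table, samples = bio_ids))
  scaled <- pareto_scale(bio$abundances)
  y <- bio$groups

  n_comp <- min(7, nrow(scaled$values) - 1, ncol(scaled$values))
  pca <- fit_pca(scaled, n_components = n_comp, cv_folds = config$cv_folds)
  opls <- fit_oplsda(scaled, y, k_orth = config$k_orth,
                     cv_folds = config$cv_folds)
  perm <- if (config$n_permutations >= 20) {
    permutation_test(scaled, y, k_orth = opls$k_orth,
                     cv_folds = config$cv_folds,
                     n_perm = config$n_permutations, seed = config$seed)
  } else NULL

  vip_ids <- select_vip(opls, config$vip_threshold)
  if (length(vip_ids) < 2) {
    stop("pipeline stage 'vip': fewer than 2 features passed VIP > ",
         config$vip_threshold, call. = FALSE)
  }
  x_vip <- bio$abundances[, vip_ids, drop = FALSE]
  rf_log <- iterate_rf_importance(x_vip, y,
                                  n_iterations = config$rf_iterations,
                                  n_trees = config$rf_trees,
                                  seed = config$seed)
  selected <- top1_select(rf_log, config$min_frequency)
  if (length(selected) < 1) {
    stop("pipeline stage 'rfselect': no feature reached the rank-1 ",
         "frequency threshold", call. = FALSE)
  }
  final <- final_model_eval(bio$abundances[, selected, drop = FALSE], y,
                            n_trees = config$rf_trees, seed = config$seed)

  report <- structure(
    list(
      counts = list(
        n_input = ncol(table$abundances),
        n_removed_qc_rsd = filt$report$n_removed_qc_rsd,
        n_removed_80pct = filt$report$n_removed_80pct,
        n_retained = filt$report$n_retained,
        n_significant = sum(uni$significant),
        n_vip = length(vip_ids),
        n_selected = length(selected)
      ),
      models = list(
        pca = list(n_components = pca$n_components, r2x_cum = pca$r2x_cum,
                   q2_cum = pca$q2_cum),
        oplsda = list(k_orth = opls$k_orth, r2x_cum = opls$r2x_cum,
                      r2y_cum = opls$r2y_cum, q2_cum = opls$q2_cum),
        permutation = if (!is.null(perm)) {
          list(n = perm$n_permutations, r2_intercept = perm$r2_intercept,
               q2_intercept = perm$q2_intercept, p_value = perm$p_value)
        }
      ),
      vip_features = vip_ids,
      selected_markers = selected,
      final_oob_error = final$oob_error,
      final_auc = final$auc,
      truth_recovery = if (synthetic_run) {
        truth_recovery_report(truth, selected, table$feature_ids)
      },
      seed = config$seed
    ),
    class = "pipeline_report"
  )

  if (!is.null(output_dir)) {
    .write_pipeline_artifacts(output_dir, report, filt, uni, opls, rf_log)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cn <- x$counts
  cat(sprintf(
    "pipeline: %d features -> %d retained -> %d significant (t-test) -> %d VIP > 1 -> %d selected markers\n",
    cn$n_input, cn$n_retained, cn$n_significant, cn$n_vip, cn$n_selected))
  cat(sprintf("OPLS-DA (1+%d): R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
              x$models$oplsda$k_orth, x$models$oplsda$r2x_cum,
              x$models$oplsda$r2y_cum, x$models$oplsda$q2_cum))
  cat(sprintf("final forest: OOB error = %.3f, AUC = %.3f\n",
              x$final_oob_error, x$final_auc))
  if (!is.null(x$truth_recovery)) {
    cat(sprintf("planted-marker recovery: sensitivity = %.2f, FDP = %.2f\n",
                x$truth_recovery$sensitivity, x$truth_recovery$fdp))
  }
  invisible(x)
}

.write_pipeline_artifacts <- function(dir, report, filt, uni, opls, rf_log) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(filt$report, file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(uni, file.path(dir, "univariate_results.csv"),
                   row.names = FALSE)
  vip_tab <- data.frame(feature_id = names(opls$vip), vip = unname(opls$vip))
  utils::write.csv(vip_tab[order(-vip_tab$vip), ],
                   file.path(dir, "vip.csv"), row.names = FALSE)
  utils::write.csv(opls$s_plot, file.path(dir, "s_plot.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rf_log$rankings),
                   file.path(dir, "rf_rankings.csv"), row.names = FALSE)
  invisible(NULL)
}
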