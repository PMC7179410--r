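# Synthetic two-group LC-MS feature tables with planted ground truth.
#
# The generator emulates the study design the pipeline targets: two
# biological groups (52 and 34 samples) plus pooled-QC replicates, log-normal
# feature abundances, a small set of planted group-discriminant markers, a
# subset of analytically unstable features (QC RSD above the 15% filter), and
# a subset of sparse features failing the 80% presence rule. Everything is a
# pure function of the config, so every downstream stage can be tested
# against known truth without any external data.

#' Synthetic feature-table configuration
#'
#' Defaults mirror the emulated study: 52 vs 34 biological samples, 8 pooled
#' QC injections, 400 features of which 10 are planted discriminant markers
#' at a log2 fold change of 2, biological CV 30%, QC (technical) CV 8%, 5%
#' random missingness, 10% planted high-QC-RSD features and 5% planted
#' sparse features.
#'
#' @param n_group_a,n_group_b,n_qc Sample counts per group / QC injections.
#' @param n_features Total number of features.
#' @param n_markers Number of planted discriminant features.
#' @param log2_fold_change Planted group effect: marker features differ by
#'   this many log2 units between groups (antisymmetric, half up half down).
#' @param biological_cv Coefficient of variation of biological replicates on
#'   the natural scale, in (0,1).
#' @param qc_cv Technical CV of QC replicates, in (0,1).
#' @param missing_rate Completely-at-random missingness in biological
#'   samples, in [0,1).
#' @param frac_high_qc_rsd Fraction of features planted with QC RSD above
#'   the 15% filter threshold, in [0,1).
#' @param frac_sparse Fraction of features planted with < 80% presence in
#'   both groups, in [0,1).
#' @param seed Integer seed governing all randomness of [synthesize_table()].
#' @return A `"synthetic_config"` list.
#' @export
synthetic_config <- function(n_group_a = 52, n_group_b = 34, n_qc = 8,
                             n_features = 400, n_markers = 10,
                             log2_fold_change = 2.0,
                             biological_cv = 0.30, qc_cv = 0.08,
                             missing_rate = 0.05, frac_high_qc_rsd = 0.10,
                             frac_sparse = 0.05, seed = 1L) {
  cfg <- list(n_group_a = as.integer(n_group_a),
              n_group_b = as.integer(n_group_b),
              n_qc = as.integer(n_qc),
              n_features = as.integer(n_features),
              n_markers = as.integer(n_markers),
              log2_fold_change = log2_fold_change,
              biological_cv = biological_cv, qc_cv = qc_cv,
              missing_rate = missing_rate,
              frac_high_qc_rsd = frac_high_qc_rsd,
              frac_sparse = frac_sparse,
              seed = as.integer(seed))
  with(cfg, {
    if (n_group_a < 1 || n_group_b < 1 || n_qc < 0 || n_features < 1) {
      stop("sample and feature counts must be positive", call. = FALSE)
    }
    if (n_markers < 0 || n_markers > n_features) {
      stop("n_markers must lie in [0, n_features]", call. = FALSE)
    }
    if (biological_cv <= 0 || biological_cv >= 1 || qc_cv <= 0 || qc_cv >= 1) {
      stop("CV parameters must lie in (0, 1)", call. = FALSE)
    }
    if (missing_rate < 0 || missing_rate >= 1 ||
        frac_high_qc_rsd < 0 || frac_high_qc_rsd >= 1 ||
        frac_sparse < 0 || frac_sparse >= 1) {
      stop("rates must lie in [0, 1)", call. = FALSE)
    }
    n_planted <- n_markers + round(frac_high_qc_rsd * n_features) +
      round(frac_sparse * n_features)
    if (n_planted > n_features) {
      stop("planted marker/unstable/sparse features exceed n_features",
           call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

# sd of log2 intensity giving coefficient of variation `cv` on the natural
# scale under log-normality: sd_ln = sqrt(ln(1 + cv^2)), sd_log2 = sd_ln/ln 2
.cv_to_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Generate a synthetic feature table with known ground truth
#'
#' Log2 intensities are a per-feature baseline (uniform on [10, 20]) plus an
#' antisymmetric group effect of +/- `log2_fold_change`/2 for marker
#' features, plus Gaussian noise whose log2 sd corresponds to the requested
#' natural-scale CV. QC samples replicate the pooled (grand) profile with
#' `qc_cv`, except planted unstable features which receive a 40% technical
#' CV, far above the 15% RSD filter. Planted sparse features are set missing
#' in 30% of the samples of each biological group (presence 70% < 80%); all
#' other biological cells are censored completely at random at
#' `missing_rate`. QC cells outside the unstable set are never censored.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `table` (a `feature_table`) and `truth`
#'   (marker/unstable/sparse feature-id lists; the three sets are disjoint).
#' @export
synthesize_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  p <- config$n_features
  n_a <- config$n_group_a
  n_b <- config$n_group_b
  n_bio <- n_a + n_b
  feature_ids <- sprintf("F%04d", seq_len(p))

  n_unstable <- round(config$frac_high_qc_rsd * p)
  n_sparse <- round(config$frac_sparse * p)
  pool <- sample.int(p)   # disjoint planted sets by construction
  markers <- sort(pool[seq_len(config$n_markers)])
  unstable <- sort(pool[config$n_markers + seq_len(n_unstable)])
  sparse <- sort(pool[config$n_markers + n_unstable + seq_len(n_sparse)])

  baseline <- stats::runif(p, 10, 20)
  effect <- numeric(p)
  if (length(markers)) {
    # antisymmetric: half the markers up in group_a, half up in group_b
    sign <- rep(c(1, -1), length.out = length(markers))
    effect[markers] <- sign * config$log2_fold_change
  }

  sd_bio <- .cv_to_log2_sd(config$biological_cv)
  mu <- matrix(baseline, n_bio, p, byrow = TRUE)
  mu[seq_len(n_a), ] <- mu[seq_len(n_a), ] +
    matrix(effect / 2, n_a, p, byrow = TRUE)
  mu[n_a + seq_len(n_b), ] <- mu[n_a + seq_len(n_b), ] -
    matrix(effect / 2, n_b, p, byrow = TRUE)
  log2x <- mu + matrix(stats::rnorm(n_bio * p, sd = sd_bio), n_bio, p)

  # QC: replicates of the pooled profile (grand mean of the two group means)
  qc_mu <- baseline   # effects are antisymmetric, so the pooled mean is flat
  sd_qc <- rep(.cv_to_log2_sd(config$qc_cv), p)
  sd_qc[unstable] <- .cv_to_log2_sd(0.40)
  log2qc <- matrix(qc_mu, config$n_qc, p, byrow = TRUE) +
    matrix(stats::rnorm(config$n_qc * p), config$n_qc, p) *
    matrix(sd_qc, config$n_qc, p, byrow = TRUE)

  x <- rbind(2^log2x, 2^log2qc)
  rownames(x) <- c(sprintf("A%03d", seq_len(n_a)),
                   sprintf("B%03d", seq_len(n_b)),
                   sprintf("QC%02d", seq_len(config$n_qc)))
  colnames(x) <- feature_ids
  groups <- c(rep("group_a", n_a), rep("group_b", n_b),
              rep("qc", config$n_qc))

  # random censoring of biological cells (never on planted sparse features,
  # whose missingness is structured below)
  if (config$missing_rate > 0) {
    cens <- matrix(stats::runif(n_bio * p) < config$missing_rate, n_bio, p)
    cens[, sparse] <- FALSE
    x[seq_len(n_bio), ][cens] <- NA
  }
  for (f in sparse) {
    drop_a <- sample.int(n_a, floor(0.3 * n_a))
    drop_b <- sample.int(n_b, floor(0.3 * n_b))
    x[drop_a, f] <- NA
    x[n_a + drop_b, f] <- NA
  }

  list(
    table = feature_table(x, groups, feature_mz = stats::runif(p, 100, 1345),
                          feature_rt = stats::runif(p, 1, 30)),
    truth = list(
      marker_feature_ids = feature_ids[markers],
      unstable_feature_ids = feature_ids[unstable],
      sparse_feature_ids = feature_ids[sparse]
    )
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Score a marker selection against planted truth
#'
#' @param truth The `truth` element returned by [synthesize_table()].
#' @param selected Character vector of selected feature ids.
#' @param universe All feature ids of the table the selection was made from.
#' @return A list with `sensitivity` (recovered fraction of planted markers)
#'   and `fdp` (false discovery proportion of the selection).
#' @export
truth_recovery_report <- function(truth, selected, universe) {
  stopifnot(is.character(selected) | length(selected) == 0)
  unknown <- setdiff(selected, universe)
  if (length(unknown)) {
    stop("selected feature ids outside the feature universe: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  markers <- truth$marker_feature_ids
  hits <- length(intersect(selected, markers))
  list(
    sensitivity = if (length(markers)) hits / length(markers) else NA_real_,
    fdp = (length(selected) - hits) / max(1L, length(selected))
  )
}
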