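# FeatureTable: the central container. Samples are rows of the abundance
# matrix; group labels are "group_a", "group_b" or "qc"; feature metadata
# carries m/z (Th) and retention time (min). On-disk files store features as
# rows (the orientation vendor exports use) and are transposed at load.

#' Construct a feature table
#'
#' @param abundances Numeric matrix, samples x features; `NA` marks missing
#'   cells, all observed values must be >= 0.
#' @param groups Character vector, one per sample, each `"group_a"`,
#'   `"group_b"` or `"qc"`.
#' @param feature_mz Positive numeric, one m/z (Th) per feature.
#' @param feature_rt Non-negative numeric, one retention time (min) per
#'   feature.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(abundances, groups, feature_mz, feature_rt) {
  stopifnot(is.matrix(abundances), is.numeric(abundances))
  sample_ids <- rownames(abundances)
  feature_ids <- colnames(abundances)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("abundance matrix must carry sample (row) and feature (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (length(groups) != nrow(abundances)) {
    stop("need one group label per sample", call. = FALSE)
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("group_a", "group_b", "qc"))
  if (length(bad)) {
    stop("unknown group labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(abundances < 0, na.rm = TRUE)) {
    stop("negative abundance values are not allowed", call. = FALSE)
  }
  stopifnot(length(feature_mz) == ncol(abundances),
            length(feature_rt) == ncol(abundances))
  if (any(!is.na(feature_mz) & feature_mz <= 0)) {
    stop("feature m/z must be positive", call. = FALSE)
  }
  if (any(!is.na(feature_rt) & feature_rt < 0)) {
    stop("feature retention time must be non-negative", call. = FALSE)
  }
  structure(
    list(
      abundances = abundances,
      sample_ids = sample_ids,
      groups = groups,
      feature_ids = feature_ids,
      feature_mz = as.numeric(feature_mz),
      feature_rt = as.numeric(feature_rt)
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  n_missing <- sum(is.na(x$abundances))
  cat(sprintf(
    "feature_table: %d samples (%d group_a, %d group_b, %d qc) x %d features\n",
    nrow(x$abundances), sum(x$groups == "group_a"),
    sum(x$groups == "group_b"), sum(x$groups == "qc"), ncol(x$abundances)))
  cat(sprintf("missing cells: %d (%.1f%%)\n", n_missing,
              100 * n_missing / length(x$abundances)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundances)

#' Subset a feature table by features and/or samples
#'
#' @param table A `feature_table`.
#' @param features Character vector of feature ids to keep (default all).
#' @param samples Character vector of sample ids to keep (default all).
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
subset_features <- function(table, features = table$feature_ids,
                            samples = table$sample_ids) {
  stopifnot(inherits(table, "feature_table"))
  if (!all(features %in% table$feature_ids)) {
    stop("unknown feature ids in selection", call. = FALSE)
  }
  if (!all(samples %in% table$sample_ids)) {
    stop("unknown sample ids in selection", call. = FALSE)
  }
  fi <- match(features, table$feature_ids)
  si <- match(samples, table$sample_ids)
  feature_table(table$abundances[si, fi, drop = FALSE],
                table$groups[si],
                table$feature_mz[fi], table$feature_rt[fi])
}

.map_group_labels <- function(labels) {
  lab <- tolower(trimws(labels))
  out <- ifelse(lab %in% c("qc", "pool", "pooled_qc"), "qc", lab)
  non_qc <- sort(unique(out[out != "qc"]))
  if (length(non_qc) != 2L) {
    stop("metadata must define exactly two non-QC groups, found: ",
         paste(non_qc, collapse = ", "), call. = FALSE)
  }
  out[out == non_qc[1]] <- "group_a"
  out[out == non_qc[2]] <- "group_b"
  out
}

#' Read a feature table from delimited text
#'
#' The abundance file has one row per feature with columns `feature_id`,
#' `mz`, `rt` followed by one column per sample (header row carries the
#' sample ids); blank cells are missing. The metadata file (YAML, JSON or
#' 2-column CSV) maps every sample id to a group label; labels equal to
#' `"QC"` (case-insensitive) mark pooled QC injections and the remaining two
#' labels are assigned to `group_a`/`group_b` in alphabetical order.
#'
#' @param path Path to the abundance CSV.
#' @param metadata_path Path to the sample-metadata file.
#' @return A validated `feature_table`; the on-disk features-as-rows
#'   orientation is transposed so samples are rows.
#' @export
read_feature_table <- function(path, metadata_path) {
  if (!file.exists(path)) stop("abundance file not found: ", path,
                               call. = FALSE)
  if (!file.exists(metadata_path)) stop("metadata file not found: ",
                                        metadata_path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(raw))) {
    stop("abundance file must have columns feature_id, mz, rt", call. = FALSE)
  }
  if (anyDuplicated(raw$feature_id)) {
    stop("duplicated feature id in abundance file", call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), need)
  if (anyDuplicated(sample_cols)) {
    stop("duplicated sample id in abundance file header", call. = FALSE)
  }
  meta <- .read_sample_metadata(metadata_path)
  missing_meta <- setdiff(sample_cols, names(meta))
  if (length(missing_meta)) {
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  x <- t(as.matrix(raw[, sample_cols, drop = FALSE]))
  storage.mode(x) <- "double"
  colnames(x) <- raw$feature_id
  rownames(x) <- sample_cols
  feature_table(x, .map_group_labels(meta[sample_cols]),
                as.numeric(raw$mz), as.numeric(raw$rt))
}

.read_sample_metadata <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    m <- yaml::read_yaml(path)
    if (!is.null(m$groups)) m <- m$groups
    unlist(m)
  } else if (ext == "json") {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(m$groups)) m <- m$groups
    unlist(m)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(d))) {
      stop("metadata CSV must have columns sample_id, group", call. = FALSE)
    }
    stats::setNames(d$group, d$sample_id)
  }
}

#' Write a feature table (and its metadata) to delimited text
#'
#' Inverse of [read_feature_table()]: features as rows, samples as columns,
#' missing cells blank; metadata written as YAML with the internal
#' `group_a`/`group_b`/`qc` labels.
#'
#' @param table A `feature_table`.
#' @param path Output path for the abundance CSV.
#' @param metadata_path Output path for the metadata YAML.
#' @return Invisibly, the input table.
#' @export
write_feature_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  out <- data.frame(
    feature_id = table$feature_ids,
    mz = table$feature_mz,
    rt = table$feature_rt,
    stringsAsFactors = FALSE
  )
  ab <- t(table$abundances)
  out <- cbind(out, as.data.frame(ab, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  yaml::write_yaml(
    list(groups = as.list(stats::setNames(table$groups, table$sample_ids))),
    metadata_path)
  invisible(table)
}
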