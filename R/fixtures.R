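# Packaged compound tables for the two officinal Gentiana species: the 87
# tentatively characterized constituents, the 11 screened chemical markers,
# and the sample-collection layout. All printed values are transcribed
# verbatim, including rows whose printed m/z disagrees with formula
# arithmetic — audit_fixture_mz() surfaces those instead of fixing them.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "chemomarker")
  if (!nzchar(p) || !file.exists(p)) {
    stop("packaged fixture missing or corrupt: ", file, call. = FALSE)
  }
  p
}

#' Load a packaged compound table
#'
#' `"table1"` is the full constituent characterization (87 records with
#' compound class and per-species presence flags); `"table2"` is the final
#' chemical-marker list (11 records, 4 of them unidentified and named
#' `"Unknown"`); `"table3"` is the sample-collection layout of the two
#' species.
#'
#' @param which One of `"table1"`, `"table2"`, `"table3"`.
#' @return A data.frame; for table1/table2 one row per printed compound
#'   record with `in_scabra`/`in_rigescens` as logicals (table1 only).
#' @examples
#' nrow(load_compound_fixture("table1"))  # 87
#' @export
load_compound_fixture <- function(which = c("table1", "table2", "table3")) {
  which <- match.arg(which)
  file <- switch(which,
    table1 = "table1_constituents.csv",
    table2 = "table2_markers.csv",
    table3 = "table3_samples.csv"
  )
  d <- utils::read.csv(.fixture_path(file), stringsAsFactors = FALSE,
                       colClasses = "character")
  if (which == "table3") return(d)
  d$index <- as.integer(d$index)
  d$mz <- as.numeric(d$mz)
  d$rt <- as.numeric(d$rt)
  if (which == "table1") {
    d$in_scabra <- d$in_scabra == "+"
    d$in_rigescens <- d$in_rigescens == "+"
    if (!all(d$in_scabra | d$in_rigescens)) {
      stop("corrupt fixture: constituent present in neither species",
           call. = FALSE)
    }
  }
  # every non-empty formula must parse to positive element counts
  for (f in d$formula[nzchar(d$formula)]) parse_formula(f)
  d
}

#' Count sample numbers enumerated in the collection table
#'
#' Expands the printed `sample_number` ranges (e.g. `"1-20"`) and counts
#' samples per species.
#'
#' @return Named integer vector of per-species sample counts.
#' @export
fixture_sample_counts <- function() {
  d <- load_compound_fixture("table3")
  counts <- vapply(d$sample_number, function(s) {
    parts <- as.integer(strsplit(s, "-")[[1]])
    if (length(parts) == 1L) 1L else parts[2] - parts[1] + 1L
  }, integer(1))
  tapply(counts, d$species, sum)
}
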