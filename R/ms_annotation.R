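# Monoisotopic mass arithmetic and neutral-loss annotation for
# negative-mode electrospray adducts.

# IUPAC/CODATA monoisotopic atomic masses (u). C-12 is exact by definition.
ELEMENT_MASSES <- c(
  C = 12,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200,
  Na = 22.98976928,
  Cl = 34.96885268
)

# Proton mass with the electron mass folded in: removing H+ from a neutral
# molecule subtracts 1.00727646 u. At the 2-dp reporting convention used for
# printed m/z values the electron term (0.00055 u) is not resolvable on its
# own, so it is kept inside this single constant.
PROTON_MASS <- 1.00727646

# Neutral formic acid (HCOOH = CH2O2), for the formate adduct [M-H+HCOOH]-.
FORMIC_ACID_MASS <- 46.00547930

#' Parse a molecular formula string
#'
#' Accepts plain Hill-style formulas (`"C19H18O11"`) as well as the
#' underscore-subscript dialect used in the packaged compound tables
#' (`"C_19_H_18_O_11_"`), including partially mangled mixtures of the two.
#'
#' @param text A single formula string.
#' @return An object of class `"formula_comp"`: a named integer vector of
#'   element counts (e.g. `c(C = 19, H = 18, O = 11)`).
#' @examples
#' parse_formula("C19H18O11")
#' parse_formula("C_35_H_42_O_20_")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  clean <- gsub("[_\\s]+", "", text, perl = TRUE)
  if (!nzchar(clean)) {
    stop("empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean, perl = TRUE)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L || paste(tokens, collapse = "") != clean) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- gsub("[0-9]+", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(ELEMENT_MASSES)) {
      stop("unknown element symbol '", sym, "' in formula: ", text,
           call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  if (sum(counts) <= 0L) stop("formula has no atoms: ", text, call. = FALSE)
  structure(counts, class = "formula_comp")
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula A `"formula_comp"` object from [parse_formula()], or a
#'   formula string.
#' @return Neutral monoisotopic mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "formula_comp"))
  sum(ELEMENT_MASSES[names(formula)] * as.numeric(formula))
}

.normalize_adduct <- function(adduct) {
  key <- toupper(gsub("[^A-Za-z]", "", adduct))
  if (key %in% c("MMINUSH", "MH")) return("M_minus_H")
  if (key %in% c("MPLUSFORMATE", "MHHCOOH", "MHCOOH")) return("M_plus_formate")
  stop("unknown adduct: ", adduct,
       " (expected [M-H] or [M-H+HCOOH])", call. = FALSE)
}

#' Negative-mode adduct m/z from a molecular formula
#'
#' Computes the m/z of the deprotonated ion `[M-H]-` or the formate adduct
#' `[M-H+HCOOH]-` from the neutral monoisotopic mass. Values are returned at
#' full precision; printed compound tables are compared at 2 decimals.
#'
#' @param formula A `"formula_comp"` object or formula string.
#' @param adduct One of `"M_minus_H"` / `"[M-H]"` or `"M_plus_formate"` /
#'   `"[M-H+HCOOH]"`.
#' @return The ion m/z (Th).
#' @examples
#' round(monoisotopic_mz("C19H18O11", "[M-H]"), 2)       # 421.08
#' round(monoisotopic_mz("C16H20O9", "[M-H+HCOOH]"), 2)  # 401.11
#' @export
monoisotopic_mz <- function(formula, adduct = "M_minus_H") {
  m <- monoisotopic_mass(formula)
  switch(.normalize_adduct(adduct),
    M_minus_H = m - PROTON_MASS,
    M_plus_formate = m + FORMIC_ACID_MASS - PROTON_MASS
  )
}

#' Library of common neutral losses
#'
#' Exact masses of detachable moieties recurring in glycoside fragmentation:
#' water, formaldehyde, ketene (deacetylation), CO2, the C3H6O3 cross-ring
#' sugar loss, an anhydroglucose unit (de-saccharification of O-glucosides),
#' an anhydro-dihydroxybenzoyl unit, and a caffeoyl unit.
#'
#' @param extra Optional named numeric vector of additional losses (u).
#' @return A data.frame with columns `name` and `mass`.
#' @export
neutral_loss_library <- function(extra = NULL) {
  losses <- c(
    H2O = 18.0106,
    CH2O = 30.0106,
    C2H2O = 42.0106,
    CO2 = 43.9898,
    C3H6O3 = 90.0317,
    anhydroglucose = 162.0528,
    anhydro_dihydroxybenzoyl = 136.0160,
    caffeoyl = 162.0317
  )
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)), all(extra > 0))
    losses <- c(losses, extra)
  }
  if (anyDuplicated(names(losses))) {
    stop("duplicate loss names", call. = FALSE)
  }
  data.frame(name = names(losses), mass = unname(losses),
             stringsAsFactors = FALSE)
}

#' Explain fragment ions as neutral losses from a precursor
#'
#' For each fragment m/z, matches the mass difference to the precursor
#' against single losses and ordered chains of up to two losses from the
#' library, within a tolerance. The closest match wins; unmatched fragments
#' are labelled `"unexplained"`.
#'
#' @param precursor_mz Precursor ion m/z (Th); must exceed every fragment.
#' @param fragment_mzs Numeric vector of fragment m/z values.
#' @param library Loss library data.frame, see [neutral_loss_library()].
#' @param tol Match tolerance in Th (default 0.02).
#' @return A data.frame with one row per fragment: `fragment_mz`, `delta`,
#'   `losses` (slash-separated names or `"unexplained"`), `mass_error`.
#' @export
explain_losses <- function(precursor_mz, fragment_mzs,
                           library = neutral_loss_library(), tol = 0.02) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            is.numeric(fragment_mzs), length(fragment_mzs) >= 1L)
  if (any(fragment_mzs >= precursor_mz)) {
    stop("every fragment m/z must be smaller than the precursor m/z",
         call. = FALSE)
  }
  single <- library$mass
  names(single) <- library$name
  # all ordered-insensitive chains of length two (including a loss twice)
  idx <- which(upper.tri(matrix(0, nrow(library), nrow(library)), diag = TRUE),
               arr.ind = TRUE)
  pair_mass <- library$mass[idx[, 1]] + library$mass[idx[, 2]]
  pair_name <- paste(library$name[idx[, 1]], library$name[idx[, 2]], sep = "/")

  out <- lapply(fragment_mzs, function(f) {
    delta <- precursor_mz - f
    cand_mass <- c(single, stats::setNames(pair_mass, pair_name))
    err <- abs(delta - cand_mass)
    # prefer single losses when both a single and a chain fit
    ord <- order(err + ifelse(seq_along(err) > length(single), 1e-9, 0))
    best <- ord[1]
    if (err[best] <= tol) {
      data.frame(fragment_mz = f, delta = delta,
                 losses = names(cand_mass)[best],
                 mass_error = delta - cand_mass[[best]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(fragment_mz = f, delta = delta, losses = "unexplained",
                 mass_error = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Audit printed m/z values against formula arithmetic
#'
#' Recomputes the adduct m/z of every compound record that carries a formula
#' and compares it with the printed value. Records deviating by more than
#' `tol` are flagged; they are reported, never corrected — several printed
#' table rows are internally inconsistent and the discrepancy is the finding.
#'
#' @param records A compound-record data.frame from [load_compound_fixture()].
#' @param tol Flagging threshold in Th (default 0.02).
#' @return A data.frame with `index`, `name`, `formula`, `adduct`,
#'   `printed_mz`, `computed_mz`, `abs_diff`, `flagged`.
#' @export
audit_fixture_mz <- function(records, tol = 0.02) {
  stopifnot(is.data.frame(records),
            all(c("name", "formula", "mz", "adduct") %in% names(records)))
  has_formula <- !is.na(records$formula) & nzchar(records$formula)
  rec <- records[has_formula, , drop = FALSE]
  computed <- mapply(function(f, a) monoisotopic_mz(parse_formula(f), a),
                     rec$formula, rec$adduct)
  out <- data.frame(
    index = rec$index,
    name = rec$name,
    formula = rec$formula,
    adduct = rec$adduct,
    printed_mz = rec$mz,
    computed_mz = round(unname(computed), 4),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$abs_diff <- abs(out$computed_mz - out$printed_mz)
  out$flagged <- out$abs_diff > tol
  out
}
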