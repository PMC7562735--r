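# Molecular-formula arithmetic: parsing, average / monoisotopic mass,
# and protonation-adduct m/z for ESI-MS identification tables.

# IUPAC standard atomic weights (conventional values) and monoisotopic
# masses of the elements that occur in small-molecule natural products.
.ATOMIC_WEIGHTS <- c(
  H = 1.008,   C = 12.011,  N = 14.007,  O = 15.999,  F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974,  S = 32.06,
  Cl = 35.45,  K = 39.098,  Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Cu = 63.546, Zn = 65.38,  Se = 78.971, Br = 79.904, I = 126.904
)

.MONOISOTOPIC_MASSES <- c(
  H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
  F = 18.9984032, Na = 22.98976928, Mg = 23.9850417, Si = 27.9769265,
  P = 30.97376151, S = 31.97207069, Cl = 34.96885271, K = 38.9637069,
  Ca = 39.9625912, Mn = 54.9380496, Fe = 55.9349421, Cu = 62.9296011,
  Zn = 63.9291466, Se = 79.9165218, Br = 78.9183376, I = 126.904468
)

# Mass of a proton in Da; [M+H]+ / [M-H]- shifts are +/- this value.
.PROTON_MASS <- 1.00728

#' Parse a molecular formula
#'
#' Parses Hill-style molecular formulas such as `"C23H28O11"`. Underscore
#' subscript markers as found in typesetting exports (`"C_23_H_28_O_11_"`)
#' and surrounding whitespace are tolerated, as is a trailing charge sign
#' (`"+"` or `"-"`), which is recorded but carries no mass.
#'
#' @param text A single formula string.
#' @return An object of class `chem_formula`: a named integer vector of
#'   element counts with a `charge` attribute (`"+"`, `"-"` or `""`).
#' @examples
#' parse_formula("C9H8O3")
#' parse_formula("C_23_H_28_O_11_")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  s <- gsub("[_[:space:]]", "", text)
  charge <- ""
  if (grepl("[+-]$", s)) {
    charge <- substring(s, nchar(s))
    s <- substring(s, 1L, nchar(s) - 1L)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", text, call. = FALSE)
  elements <- sub("[0-9]*$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elements, names(.ATOMIC_WEIGHTS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  out <- stats::setNames(as.integer(out), names(out))
  structure(out, charge = charge, class = "chem_formula")
}

#' Format a parsed formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical when no carbon is present), with any charge suffix.
#'
#' @param f A `chem_formula` from [parse_formula()].
#' @return A single formula string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  els <- names(f)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  n <- unclass(f)[ord]
  paste0(paste0(ord, ifelse(n == 1L, "", n), collapse = ""), attr(f, "charge"))
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Molecular mass of a formula
#'
#' Sum of per-element masses. The default uses IUPAC standard atomic
#' weights (average mass, the style of database MW columns); monoisotopic
#' mode uses the most abundant isotope of each element, the style of
#' high-resolution MS identification tables.
#'
#' @param f A `chem_formula` or a formula string (parsed on the fly).
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da (numeric scalar).
#' @examples
#' molecular_mass("C10H10O4")          # 194.186
#' molecular_mass("C23H28O11", "monoisotopic")
#' @export
molecular_mass <- function(f, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  tab <- if (mode == "average") .ATOMIC_WEIGHTS else .MONOISOTOPIC_MASSES
  sum(tab[names(f)] * as.numeric(f))
}

#' Protonation-adduct m/z
#'
#' m/z of the singly protonated / deprotonated ion:
#' `[M+H]+ = MW + 1.00728`, `[M-H]- = MW - 1.00728`.
#'
#' @param mw Neutral molecular mass in Da (positive numeric, vectorized).
#' @param ion `"M+H"` or `"M-H"` (also accepts `"M-H"` spelled with a
#'   minus sign or hyphen).
#' @return m/z at full precision; round to 2 decimals for reporting.
#' @examples
#' round(adduct_mz(480.16, "M+H"), 2)  # 481.17
#' round(adduct_mz(624.20, "M-H"), 2)  # 623.19
#' @export
adduct_mz <- function(mw, ion) {
  if (!is.numeric(mw) || any(!is.finite(mw)) || any(mw <= 0))
    stop("`mw` must be positive and finite", call. = FALSE)
  ion <- gsub("−", "-", ion)  # unicode minus
  if (length(ion) == 1L) ion <- rep(ion, length(mw))
  shift <- ifelse(ion == "M+H", .PROTON_MASS,
                  ifelse(ion == "M-H", -.PROTON_MASS, NA_real_))
  if (any(is.na(shift)))
    stop("unknown ion label(s): ", paste(unique(ion[is.na(shift)]), collapse = ", "),
         "; expected \"M+H\" or \"M-H\"", call. = FALSE)
  mw + shift
}

#' Check adduct tables for ion-label consistency
#'
#' For each row of an identification table (MW, printed m/z, ion label),
#' recomputes the m/z implied by the label and flags rows where the printed
#' shift contradicts it — e.g. a row labelled `M-H` whose printed m/z sits
#' one mass unit *above* the MW. Inconsistent rows are flagged, never
#' silently corrected.
#'
#' @param mw,mz Numeric vectors of neutral mass and printed m/z.
#' @param ion Character vector of ion labels (`"M+H"` / `"M-H"`).
#' @param tol Agreement tolerance in Da applied to the printed values
#'   (default 0.01, i.e. the 2-decimal reporting precision).
#' @return A data frame with the inputs, the expected m/z for the stated
#'   label, and a logical `consistent` column.
#' @export
check_adduct_consistency <- function(mw, mz, ion, tol = 0.01) {
  expected <- adduct_mz(mw, ion)
  data.frame(
    mw = mw, mz = mz, ion = ion,
    expected_mz = round(expected, 2),
    consistent = abs(mz - expected) <= tol + 1e-9,
    stringsAsFactors = FALSE
  )
}
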