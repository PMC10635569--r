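## Elemental formulas
##
## Formulas are stored as strings ("C6H12O6", "C3H7NO3", "R") and parsed into
## named numeric vectors of element counts on demand. Counts may be fractional
## (averaged lipid species); the pseudo-element "R" denotes a cycled carrier
## moiety (tRNAs, acyl-carrier proteins) and contributes zero mass.

# Standard atomic weights (IUPAC 2021, conventional values), g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Se = 78.971, Cl = 35.45, Br = 79.904, I = 126.904, F = 18.998,
  Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078, Fe = 55.845,
  Zn = 65.38, Cu = 63.546, Mn = 54.938, Mo = 95.95, Co = 58.933,
  Ni = 58.693, W = 183.84,
  R = 0 # carrier pseudo-element: cycled, never weighed
)

#' Parse an elemental formula string
#'
#' Accepts Hill-style formulas such as `"C6H12O6"`, fractional counts such as
#' `"C17.1H32.6O2"` (averaged lipids), and the pseudo-element `"R"` used for
#' cycled carrier molecules. `NA` or `""` denotes an unknown formula.
#'
#' @param formula A single formula string, or `NA` for unknown.
#' @return A named numeric vector of non-negative element counts, or `NULL`
#'   when the formula is unknown.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C6H10O5R")  # carrier-bound glucosyl unit
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() takes a single string")
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  consumed <- sum(nchar(tokens))
  if (consumed != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  elems <- sub("^([A-Z][a-z]?).*$", "\\1", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
  if (anyNA(counts) || any(counts < 0)) stop("malformed formula: '", formula, "'")
  out <- tapply(counts, elems, sum)
  structure(as.numeric(out), names = names(out))
}

#' Molar mass of a formula
#'
#' Computed from standard atomic weights; the carrier pseudo-element `R`
#' weighs zero (carriers are cycled, not consumed, so their mass never enters
#' biomass accounting).
#'
#' @param formula Formula string or parsed named count vector.
#' @return Molar mass in g/mol, or `NA` if the formula is unknown or contains
#'   an element without a tabulated weight.
#' @export
molar_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(counts)) return(NA_real_)
  w <- .ATOMIC_WEIGHTS[names(counts)]
  if (anyNA(w)) return(NA_real_)
  sum(w * counts)
}

#' Count of one element in a formula
#'
#' @param formula Formula string.
#' @param element Element symbol, e.g. `"C"`.
#' @return The count (0 when absent), or `NA` when the formula is unknown.
#' @export
element_count <- function(formula, element) {
  counts <- parse_formula(formula)
  if (is.null(counts)) return(NA_real_)
  if (element %in% names(counts)) counts[[element]] else 0
}
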