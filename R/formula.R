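#' @keywords internal
#' Monoisotopic masses (most abundant isotope), IUPAC/CODATA values.
.monoisotopic <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Cl = 34.96885268, S = 31.97207100, P = 30.97376163,
  Br = 78.9183371, I = 126.904473, B = 11.0093054, Si = 27.9769265325
)

#' Standard atomic weights (average masses), for molecular weight.
#' @keywords internal
.avg_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403,
  Cl = 35.45, S = 32.06, P = 30.973762, Br = 79.904, I = 126.90447,
  B = 10.81, Si = 28.085
)

.proton_mass <- 1.007276466

#' Parse a molecular formula into element counts
#'
#' Decomposes a Hill-style molecular formula such as `"C20H22ClN7O2"` into a
#' named integer vector of element counts. Element symbols are one capital
#' letter optionally followed by one lowercase letter; a missing count means
#' one atom.
#'
#' @param formula character scalar, e.g. `"C20H22ClN7O2"` or `"H2O"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C20H22ClN7O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?|[0-9]+|.", formula))[[1]]
  counts <- integer(0)
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (!grepl("^[A-Z][a-z]?$", tok)) {
      stop("invalid token '", tok, "' in formula '", formula, "'")
    }
    if (!tok %in% names(.monoisotopic)) {
      stop("unknown element symbol '", tok, "' in formula '", formula, "'")
    }
    n <- 1L
    if (i < length(tokens) && grepl("^[0-9]+$", tokens[i + 1L])) {
      n <- as.integer(tokens[i + 1L])
      i <- i + 1L
    }
    counts[tok] <- (if (tok %in% names(counts)) counts[[tok]] else 0L) + n
    i <- i + 1L
  }
  counts
}

#' Deparse element counts back into a Hill-order formula string
#'
#' @param counts named integer vector as returned by [parse_formula()].
#' @return Character scalar (C first, then H, then other elements
#'   alphabetically - the Hill convention).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

#' Theoretical monoisotopic m/z of the protonated molecule [M+H]+
#'
#' Sums monoisotopic atomic masses over the element counts of a neutral
#' molecule and adds one proton mass (1.007276 u; the electron mass is
#' neglected, which matches HRMS "Calcd" values at 4 decimals).
#'
#' @param counts molecular formula string or named count vector
#'   from [parse_formula()].
#' @return m/z of \[M+H\]+ as a double (not rounded).
#' @examples
#' round(monoisotopic_mh("C20H22ClN7O2"), 4) # 428.1596
#' @export
monoisotopic_mh <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (length(counts) == 0L) return(.proton_mass)
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(.monoisotopic[names(counts)] * counts) + .proton_mass
}

#' Average molecular weight from element counts
#' @param counts formula string or named count vector.
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  unknown <- setdiff(names(counts), names(.avg_mass))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(.avg_mass[names(counts)] * counts)
}
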