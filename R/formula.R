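#' @title Molecular formulas and monoisotopic masses
#' @name formula
#' @description
#' A formula is represented as a named integer vector of element counts
#' (class `fr_formula`), ordered by Hill convention (C, H, then
#' alphabetical). Masses are monoisotopic: the mass of the most abundant
#' isotope of each element, from a bundled IUPAC/CODATA constants table.
NULL

# Monoisotopic isotope masses (Da) of the most abundant isotope.
.ELEMENT_MASSES <- c(
  H  = 1.0078250319, C  = 12.0,          N  = 14.0030740052,
  O  = 15.9949146221, F  = 18.9984031630, Na = 22.9897692820,
  Mg = 23.9850417,   Al = 26.9815384,    Si = 27.9769265327,
  P  = 30.97376151,  S  = 31.97207069,   Cl = 34.96885271,
  K  = 38.9637064864, Ca = 39.9625909,   Cr = 51.9405119,
  Mn = 54.9380496,   Fe = 55.9349421,    Co = 58.9332002,
  Ni = 57.9353479,   Cu = 62.9296011,    Zn = 63.9291466,
  As = 74.9215964,   Se = 79.9165218,    Br = 78.9183376,
  I  = 126.904473,   B  = 11.0093055,    Li = 7.016004
)

#' Proton mass used for ion/neutral conversion
#'
#' Stored at 1.00728 Da; displays as 1.007 at three decimals.
#' @export
PROTON_MASS <- 1.00728

.hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  c(intersect(c("C", "H"), elements), rest)
}

#' Construct a molecular formula
#'
#' @param counts named integer vector or list, element symbol -> count.
#'   Zero counts are dropped; negative counts are an error.
#' @return an `fr_formula`: named integer vector in Hill order.
#' @examples
#' as_formula(c(C = 15, H = 12, O = 5))
#' @export
as_formula <- function(counts) {
  if (is.character(counts) && is.null(names(counts))) {
    stopifnot(length(counts) == 1)
    return(parse_formula(counts))
  }
  counts <- unlist(counts)
  if (length(counts) == 0) {
    return(structure(integer(0), class = "fr_formula"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    stop("negative element count in formula: ",
         paste(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.ELEMENT_MASSES))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ord <- .hill_order(names(counts))
  structure(stats::setNames(as.integer(counts[ord]), ord),
            class = "fr_formula")
}

#' Parse a formula string such as "C15H12O5"
#'
#' @param x a single formula string.
#' @return an `fr_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (x == "" || is.na(x)) return(as_formula(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (paste(toks, collapse = "") != x) {
    stop("cannot parse formula string: ", x, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct[ct == ""] <- "1"
  as_formula(stats::setNames(as.integer(ct), el))
}

#' Format a formula as a Hill-order string
#'
#' @param f an `fr_formula` (or named count vector).
#' @return a single string, e.g. `"C15H12O5"`; `""` for the empty formula.
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.fr_formula <- function(x, ...) {
  cat("<formula> ", formula_string(x), "  (",
      format(monoisotopic_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' @export
format.fr_formula <- function(x, ...) formula_string(x)

#' Sum / difference of formulas
#'
#' @param a,b formulas (or named count vectors).
#' @return an `fr_formula`. `formula_subtract()` errors if any count would
#'   go negative.
#' @export
formula_add <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  as_formula(c(unclass(a), unclass(b)))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  neg <- stats::setNames(-as.integer(b), names(b))
  as_formula(c(unclass(a), neg))
}

#' Monoisotopic mass of a formula, molecule or fragment table row
#'
#' Sum over elements of count times the monoisotopic isotope mass.
#'
#' @param f an `fr_formula`, a formula string, a named count vector, or an
#'   `fr_mol`.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C15H12O5"))  # 272.068
#' monoisotopic_mass("H2O")                      # 18.0106
#' @export
monoisotopic_mass <- function(f) {
  if (inherits(f, "fr_mol")) f <- formula_of(f)
  if (is.character(f)) f <- parse_formula(f)
  f <- as_formula(f)
  if (length(f) == 0) return(0)
  sum(.ELEMENT_MASSES[names(f)] * as.numeric(f))
}

#' Monoisotopic mass of a single element symbol
#' @param element element symbol, e.g. "C".
#' @return mass in Da.
#' @keywords internal
element_mass <- function(element) {
  m <- .ELEMENT_MASSES[element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(element[is.na(m)], collapse = ", "), call. = FALSE)
  }
  unname(m)
}
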