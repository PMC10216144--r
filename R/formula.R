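# Elemental-formula arithmetic and monoisotopic masses.

# Monoisotopic atomic masses (Da), CODATA/AME values. C is exactly 12 by
# definition of the unified atomic mass unit.
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  O = 15.9949146196,
  P = 30.97376163,
  N = 14.0030740048,
  S = 31.97207100
)

#' Mass of the proton (Da)
#'
#' Hydrogen atom minus one electron; used to compute m/z of deprotonated ions.
#' @export
PROTON_MASS <- 1.00727646688

#' Mass of the electron (Da)
#' @export
ELECTRON_MASS <- 0.00054857991

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector mapping element symbols
#' (`C`, `H`, `O`, `P`, ...) to non-negative counts. Formulas support `+` and
#' `-`; subtraction that would drive any count negative is an error.
#'
#' @param ... element counts as named arguments, e.g. `elemental_formula(C = 81, H = 150, O = 17, P = 2)`.
#' @return An object of class `elemental_formula`.
#' @examples
#' h2o <- elemental_formula(H = 2, O = 1)
#' monoisotopic_mass(h2o)
#' @export
elemental_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0L) {
    out <- integer(0)
    names(out) <- character(0)
    return(structure(out, class = "elemental_formula"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all element counts must be named")
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  # canonical Hill-ish order: C, H, then alphabetical
  nm <- names(counts)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  structure(counts[ord], class = "elemental_formula")
}

#' Parse a formula string such as "C81H150O17P2"
#'
#' @param x a character scalar; element symbols followed by optional counts.
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("[ _]", "", x)
  toks <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(x))
    stop("cannot parse formula string: ", x)
  syms <- sub("[0-9]*$", "", toks)
  cnts <- as.integer(ifelse(grepl("[0-9]$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(cnts, syms, sum)
  do.call(elemental_formula, as.list(counts))
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty formula)")
  n <- unclass(x)
  paste0(names(n), ifelse(n == 1L, "", n), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  counts <- structure(rep(0L, length(els)), names = els)
  counts[names(e1)] <- counts[names(e1)] + unclass(e1)
  counts[names(e2)] <- counts[names(e2)] + unclass(e2)
  do.call(elemental_formula, as.list(counts))
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is undefined for formulas")
  els <- union(names(e1), names(e2))
  counts <- structure(rep(0L, length(els)), names = els)
  counts[names(e1)] <- counts[names(e1)] + unclass(e1)
  counts[names(e2)] <- counts[names(e2)] - unclass(e2)
  if (any(counts < 0))
    stop("formula subtraction yields negative count for: ",
         paste(els[counts < 0], collapse = ", "))
  do.call(elemental_formula, as.list(counts))
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  canon <- function(e) {
    if (is.character(e)) e <- parse_formula(e)
    stopifnot(inherits(e, "elemental_formula"))
    n <- unclass(e)
    n[order(names(n))]
  }
  identical(canon(e1), canon(e2))
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times tabulated monoisotopic atomic mass over elements;
#' additive over formula addition.
#'
#' @param formula an [elemental_formula()] (or string parseable by
#'   [parse_formula()]).
#' @return Mass in Da (0 for the empty formula).
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "elemental_formula"))
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.MONO_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(unclass(formula) * .MONO_MASS[names(formula)])
}

#' m/z of the doubly deprotonated ion [M - 2H]^2-
#'
#' @param neutral_mass monoisotopic mass of the neutral species (Da).
#' @return `(neutral_mass - 2 * PROTON_MASS) / 2`.
#' @export
mz_doubly_deprotonated <- function(neutral_mass) {
  mz <- (neutral_mass - 2 * PROTON_MASS) / 2
  if (any(mz < 0)) stop("neutral mass below the mass of two protons")
  mz
}

#' Signed mass error in parts per million
#'
#' Positive when the measured value exceeds the reference exact value.
#'
#' @param measured measured m/z.
#' @param exact reference exact m/z (> 0).
#' @return Signed ppm error; compare `abs()` against a tolerance.
#' @export
ppm_error <- function(measured, exact) {
  if (any(exact <= 0)) stop("exact m/z must be positive")
  1e6 * (measured - exact) / exact
}

#' Round to printed precision
#'
#' Reproduces table-style printing of exact m/z values: round half away from
#' zero to 5 decimals, then 4, then `digits`. The staged (double) rounding
#' matters at the boundary: 713.49449 prints as 713.495.
#'
#' @param x numeric vector.
#' @param digits final number of decimals (default 3).
#' @return Rounded numeric vector.
#' @export
round_printed <- function(x, digits = 3) {
  half_away <- function(v, d) {
    p <- 10^d
    sign(v) * floor(abs(v) * p + 0.5) / p
  }
  for (d in seq(5, digits)) x <- half_away(x, d)
  x
}
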