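#' Monoisotopic element masses
#'
#' Monoisotopic masses (amu) of the elements supported by the package,
#' plus the electron mass. Deuterium is treated as its own symbol \code{"D"},
#' counted separately from \code{"H"}. Values are the standard CODATA/IUPAC
#' constants; the table is a read-only constant.
#'
#' @return Named numeric vector of monoisotopic masses in amu.
#' @examples
#' element_masses()[["C"]]  # 12 exactly
#' @export
element_masses <- function() .ISO_ELEMENTS

.ISO_ELEMENTS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  D  = 2.01410177785,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  F  = 18.99840322,
  P  = 30.97376163,
  Cl = 34.96885268,
  Br = 78.9183371,
  Na = 22.9897692809,
  K  = 38.96370668,
  Si = 27.9769265325,
  I  = 126.904473
)

#' Electron mass in amu
#'
#' @return The electron rest mass, 5.48579909e-4 amu.
#' @export
electron_mass <- function() 5.48579909e-4

# proton mass = H minus one electron; used for neutral <-> [M+/-H] conversion
.ISO_PROTON <- 1.00782503207 - 5.48579909e-4

# valences used for ring-plus-double-bond equivalents
.ISO_VALENCE <- c(C = 4, H = 1, D = 1, N = 3, O = 2, S = 2, F = 1, P = 3,
                  Cl = 1, Br = 1, I = 1)

#' Parse an elemental formula string
#'
#' Parses strings such as \code{"C19H20N2O3S"} into a named integer vector of
#' element counts. Element symbols are case sensitive, an omitted count means
#' 1, and \code{"D"} denotes deuterium, counted separately from \code{"H"}.
#'
#' @param text Formula string.
#' @return A \code{formula_counts} object: named integer vector of counts.
#' @examples
#' parse_formula("C19H20N2O3S")
#' parse_formula("C18H16D4N2O3S")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("formula must be a single non-empty string", call. = FALSE)
  text <- trimws(text)
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (nchar(paste0(toks, collapse = "")) != nchar(text))
    stop("malformed formula string: '", text, "'", call. = FALSE)
  counts <- integer(0)
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    if (!el %in% names(.ISO_ELEMENTS))
      stop("unknown element symbol '", el, "' in formula '", text, "'",
           call. = FALSE)
    ntxt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(ntxt)) as.integer(ntxt) else 1L
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    stop("formula '", text, "' has no atoms", call. = FALSE)
  structure(counts, class = "formula_counts")
}

#' Serialize element counts to a Hill-order formula string
#'
#' Hill order: carbon first, then hydrogen (with deuterium immediately after
#' hydrogen), then the remaining elements alphabetically. Counts of 1 are
#' implicit. Inverse of [parse_formula()].
#'
#' @param f Named integer vector of element counts (or `formula_counts`).
#' @return Formula string.
#' @examples
#' format_formula(parse_formula("H20C19SO3N2"))  # "C19H20N2O3S"
#' @export
format_formula <- function(f) {
  f <- .as_counts(f)
  els <- names(f)
  first <- intersect(c("C", "H", "D"), els)
  rest <- sort(setdiff(els, first))
  ord <- c(first, rest)
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

.as_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) || any(!names(f) %in% names(.ISO_ELEMENTS)))
    stop("element counts must be named with known element symbols",
         call. = FALSE)
  n <- as.integer(round(f))
  if (any(n < 0L)) stop("element counts must be non-negative", call. = FALSE)
  names(n) <- names(f)
  n <- n[n > 0L]
  if (length(n) == 0L) stop("formula has no atoms", call. = FALSE)
  structure(n, class = "formula_counts")
}

#' @export
print.formula_counts <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Sum two formulas
#'
#' @param f1,f2 Formulas (strings or count vectors).
#' @return Combined `formula_counts`.
#' @keywords internal
#' @export
formula_add <- function(f1, f2) {
  f1 <- .as_counts(f1); f2 <- .as_counts(f2)
  els <- union(names(f1), names(f2))
  out <- vapply(els, function(el) {
    a <- if (el %in% names(f1)) f1[[el]] else 0L
    b <- if (el %in% names(f2)) f2[[el]] else 0L
    a + b
  }, integer(1))
  .as_counts(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times monoisotopic element masses.
#'
#' @param f Formula string or named count vector.
#' @return Mass in amu.
#' @examples
#' monoisotopic_mass("C19H20N2O3S")  # 356.119465 to 1e-5 amu
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_counts(f)
  sum(.ISO_ELEMENTS[names(f)] * as.numeric(f))
}

#' m/z of a singly charged ion from its ion formula
#'
#' The formula is the elemental composition of the charged species itself
#' (already +H or -H relative to the neutral molecule for protonated or
#' deprotonated ions). Positive ions lack one electron, negative ions carry
#' one extra; the electron mass is subtracted or added accordingly.
#'
#' @param ion_formula Formula of the charged species.
#' @param polarity `"positive"`, `"negative"` or `"neutral"`.
#' @return m/z in amu (|z| = 1).
#' @examples
#' ion_mass("C18H23N2O3", "positive")  # 315.17032
#' ion_mass("C21H20FO9", "negative")   # 435.10968
#' @export
ion_mass <- function(ion_formula, polarity = c("positive", "negative",
                                               "neutral")) {
  polarity <- match.arg(polarity)
  m <- monoisotopic_mass(ion_formula)
  switch(polarity,
         positive = m - electron_mass(),
         negative = m + electron_mass(),
         neutral = m)
}

#' Signed ppm difference between a theoretical and an observed mass
#'
#' Computed as (theoretical - observed) / observed * 1e6.
#'
#' @param theoretical,observed Masses in amu; `observed` must be > 0.
#' @return Signed ppm.
#' @examples
#' ppm_diff(315.17032, 315.17012)  # 0.63 to 2 dp
#' @export
ppm_diff <- function(theoretical, observed) {
  if (any(observed <= 0)) stop("observed mass must be > 0", call. = FALSE)
  (theoretical - observed) / observed * 1e6
}

#' Mass defect of a metabolite relative to its parent
#'
#' The difference of the fractional (after-decimal) parts of the two
#' monoisotopic masses, in mDa: (frac(metabolite) - frac(parent)) * 1000.
#' Fractional parts are taken by truncation toward zero.
#'
#' @param metabolite_mass,parent_mass Neutral monoisotopic masses in amu, > 0.
#' @return Defect in mDa (signed).
#' @examples
#' mass_defect_from_parent(314.163043, 356.119465)  # 43.6 to 1 dp
#' @export
mass_defect_from_parent <- function(metabolite_mass, parent_mass) {
  if (any(metabolite_mass <= 0) || any(parent_mass <= 0))
    stop("masses must be > 0", call. = FALSE)
  frac <- function(x) x - trunc(x)
  (frac(metabolite_mass) - frac(parent_mass)) * 1000
}

#' Convert between ion m/z and neutral monoisotopic mass
#'
#' Assumes singly charged protonated (\code{[M+H]+}) or deprotonated
#' (\code{[M-H]-}) species: the proton mass (H minus one electron) is
#' subtracted from positive-ion m/z and added to negative-ion m/z.
#'
#' @param mz Ion m/z in amu.
#' @param polarity `"positive"` or `"negative"`.
#' @return Neutral monoisotopic mass in amu.
#' @examples
#' neutral_mass(315.17012, "positive")
#' @export
neutral_mass <- function(mz, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (polarity == "positive") mz - .ISO_PROTON else mz + .ISO_PROTON
}
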