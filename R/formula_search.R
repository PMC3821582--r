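#' Element bounds for formula enumeration
#'
#' @param ... Named integer ranges, each `c(min, max)` or a single max
#'   (min 0), e.g. `element_bounds(C = c(0, 40), H = 60, N = 8)`.
#' @return An `element_bounds` object: named list of `c(min, max)`.
#' @examples
#' element_bounds(C = 30, H = 50, N = 6, O = 10, S = 3)
#' @export
element_bounds <- function(...) {
  args <- list(...)
  if (length(args) == 0L)
    args <- list(C = c(0L, 40L), H = c(0L, 60L), N = c(0L, 8L),
                 O = c(0L, 15L), S = c(0L, 3L), F = c(0L, 3L))
  if (is.null(names(args)) || any(!nzchar(names(args))))
    stop("element bounds must be named", call. = FALSE)
  out <- lapply(args, function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- c(0L, x)
    if (length(x) != 2L || anyNA(x) || x[1] < 0L || x[2] < x[1])
      stop("each bound must be c(min, max) with 0 <= min <= max",
           call. = FALSE)
    x
  })
  bad <- setdiff(names(out), names(.ISO_ELEMENTS))
  if (length(bad))
    stop("unknown element(s) in bounds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (all(vapply(out, `[`, integer(1), 2) == 0L))
    stop("at least one element must have max > 0", call. = FALSE)
  structure(out, class = "element_bounds")
}

#' Parse a CLI-style element-bounds string
#'
#' Format: `"C:0-30,H:0-50,N:0-6"`.
#'
#' @param text Bounds string.
#' @return An `element_bounds` object.
#' @export
parse_element_bounds <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  args <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed element bound '", p, "'", call. = FALSE)
    rng <- as.integer(strsplit(kv[2], "-", fixed = TRUE)[[1]])
    args[[kv[1]]] <- if (length(rng) == 1L) c(0L, rng) else rng
  }
  do.call(element_bounds, args)
}

#' Ring-plus-double-bond equivalents of a formula
#'
#' RDBE = 1 + sum over elements of count * (valence - 2) / 2, with valences
#' C 4; N, P 3; O, S 2; H, D, F, Cl, Br, I 1. Used as a plausibility screen
#' for enumerated compositions (half-integer values arise for even-electron
#' ions).
#'
#' @param f Formula string or named count vector.
#' @return RDBE as a (half-)integer numeric.
#' @examples
#' rdbe("C6H6")         # 4
#' rdbe("C19H20N2O3S")  # 11
#' @export
rdbe <- function(f) {
  f <- .as_counts(f)
  bad <- setdiff(names(f), names(.ISO_VALENCE))
  if (length(bad))
    stop("no valence defined for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  1 + sum(as.numeric(f) * (.ISO_VALENCE[names(f)] - 2)) / 2
}

#' Enumerate candidate ion formulas for an observed m/z
#'
#' Exhaustive depth-first enumeration of elemental compositions within the
#' element bounds, with branch-and-bound pruning on the residual mass
#' window. The enumerated formula is the composition of the charged species
#' itself; its theoretical m/z is computed with the electron-mass correction
#' of [ion_mass()]. Candidates with RDBE below `rdbe_min` are discarded.
#' The result is ranked by |ppm| ascending, ties broken by lower heteroatom
#' (non-C, non-H) count, then by Hill-order formula string.
#'
#' @param observed_mz Observed m/z in amu (> 0), singly charged.
#' @param polarity `"positive"`, `"negative"` or `"neutral"`.
#' @param bounds An [element_bounds()] object; every element searched must
#'   have an explicit finite max.
#' @param ppm_tol Tolerance in ppm (> 0); default 5.
#' @param rdbe_min Minimum RDBE; default -0.5 (the conventional floor for
#'   even-electron ions).
#' @return data.frame with columns `formula`, `theoretical_mz`, `ppm`
#'   (signed, theoretical minus observed) and `rdbe`, best candidate first.
#' @examples
#' b <- element_bounds(C = 30, H = 50, N = 6, O = 10, S = 3)
#' head(enumerate_formulas(373.12111, "positive", b, ppm_tol = 5))
#' @export
enumerate_formulas <- function(observed_mz,
                               polarity = c("positive", "negative",
                                            "neutral"),
                               bounds = element_bounds(), ppm_tol = 5,
                               rdbe_min = -0.5) {
  polarity <- match.arg(polarity)
  if (!is.finite(observed_mz) || observed_mz <= 0)
    stop("observed_mz must be > 0", call. = FALSE)
  if (!is.finite(ppm_tol) || ppm_tol <= 0)
    stop("ppm_tol must be > 0", call. = FALSE)
  stopifnot(inherits(bounds, "element_bounds"))

  # target window on the formula (pre electron-correction) mass
  ecorr <- switch(polarity, positive = electron_mass(),
                  negative = -electron_mass(), neutral = 0)
  target <- observed_mz + ecorr
  half <- ppm_tol * 1e-6 * observed_mz
  lo <- target - half
  hi <- target + half

  els <- names(bounds)
  masses <- .ISO_ELEMENTS[els]
  ord <- order(masses, decreasing = TRUE)  # heavy elements first
  els <- els[ord]; masses <- masses[ord]
  bmin <- vapply(bounds, `[`, integer(1), 1)[ord]
  bmax <- vapply(bounds, `[`, integer(1), 2)[ord]
  # max mass contributable by elements from position i onward
  suffix_max <- rev(cumsum(rev(bmax * masses)))
  suffix_min <- rev(cumsum(rev(bmin * masses)))
  suffix_max <- c(suffix_max[-1], 0)
  suffix_min <- c(suffix_min[-1], 0)

  hits <- list()
  counts <- integer(length(els))
  recurse <- function(i, acc) {
    if (i > length(els)) {
      if (acc >= lo && acc <= hi) hits[[length(hits) + 1L]] <<- counts
      return(invisible())
    }
    m <- masses[i]
    if (i == length(els)) {
      # last element: solve the count range directly
      nlo <- max(bmin[i], ceiling((lo - acc) / m - 1e-9))
      nhi <- min(bmax[i], floor((hi - acc) / m + 1e-9))
      if (m == 0) return(invisible())
      if (nlo <= nhi) {
        for (n in nlo:nhi) {
          counts[i] <<- as.integer(n)
          tot <- acc + n * m
          if (tot >= lo && tot <= hi)
            hits[[length(hits) + 1L]] <<- counts
        }
        counts[i] <<- 0L
      }
      return(invisible())
    }
    nlo <- max(bmin[i], ceiling((lo - acc - suffix_max[i]) / m - 1e-9))
    nhi <- min(bmax[i], floor((hi - acc - suffix_min[i]) / m + 1e-9))
    if (nlo > nhi) return(invisible())
    for (n in nlo:nhi) {
      counts[i] <<- as.integer(n)
      recurse(i + 1L, acc + n * m)
    }
    counts[i] <<- 0L
  }
  recurse(1L, 0)

  if (length(hits) == 0L)
    return(data.frame(formula = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0),
                      stringsAsFactors = FALSE))
  mat <- do.call(rbind, hits)
  colnames(mat) <- els
  keep_rows <- rowSums(mat) > 0
  mat <- mat[keep_rows, , drop = FALSE]
  if (nrow(mat) == 0L)
    return(data.frame(formula = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0),
                      stringsAsFactors = FALSE))
  fm <- as.numeric(mat %*% masses)
  theo <- fm - switch(polarity, positive = electron_mass(),
                      negative = -electron_mass(), neutral = 0)
  ppm <- ppm_diff(theo, observed_mz)
  rd <- 1 + as.numeric(mat %*% (.ISO_VALENCE[els] - 2)) / 2
  hill <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    format_formula(v[v > 0])
  }, character(1))
  het <- rowSums(mat[, !els %in% c("C", "H", "D"), drop = FALSE])
  out <- data.frame(formula = hill, theoretical_mz = theo, ppm = ppm,
                    rdbe = rd, stringsAsFactors = FALSE)
  out <- out[abs(out$ppm) <= ppm_tol + 1e-12 & out$rdbe >= rdbe_min, ,
             drop = FALSE]
  het <- het[abs(ppm) <= ppm_tol + 1e-12 & rd >= rdbe_min]
  o <- order(abs(out$ppm), het, out$formula)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
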