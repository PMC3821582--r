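#' Default biotransformation list
#'
#' Conventional Phase-I/II mass shifts (hydroxylation, dehydrogenation,
#' demethylation, hydration, glucuronidation, sulfation, glutathione
#' conjugation, acetylation, oxidation to carboxylic acid) plus all pairwise
#' combinations of those single steps. The list is an input, not a fixed
#' truth: real metabolic pathways routinely fall outside it.
#'
#' @param combinations Include all two-step combinations (default `TRUE`).
#' @return data.frame with columns `name`, `delta_mass` (signed amu, applied
#'   to the parent ion m/z) and `phase`.
#' @export
default_biotransformations <- function(combinations = TRUE) {
  single <- data.frame(
    name = c("hydroxylation (+O)", "dehydrogenation (-H2)",
             "demethylation (-CH2)", "hydration (+H2O)",
             "glucuronidation (+C6H8O6)", "sulfation (+SO3)",
             "glutathione (+C10H15N3O6S)", "acetylation (+C2H2O)",
             "oxidation to acid (+O2-H2)"),
    delta_mass = c(15.994915, -2.015650, -14.015650, 18.010565,
                   176.032088, 79.956815, 305.068156, 42.010565,
                   29.974179),
    phase = c("I", "I", "I", "I", "II", "II", "II", "II", "I"),
    stringsAsFactors = FALSE)
  if (!combinations) return(single)
  n <- nrow(single)
  combos <- expand.grid(i = seq_len(n), j = seq_len(n))
  combos <- combos[combos$i <= combos$j, , drop = FALSE]
  double <- data.frame(
    name = paste(single$name[combos$i], "+", single$name[combos$j]),
    delta_mass = single$delta_mass[combos$i] + single$delta_mass[combos$j],
    phase = ifelse(single$phase[combos$i] == "II" |
                     single$phase[combos$j] == "II", "II", "I"),
    stringsAsFactors = FALSE)
  out <- rbind(single, double)
  out <- out[!duplicated(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match run features against a biotransformation list
#'
#' A feature matches a transformation when its m/z lies within `tol`
#' (inclusive) of the parent ion m/z plus the transformation's mass shift.
#' All matches are reported (a feature may match several entries).
#'
#' @param features A `feature_map`.
#' @param parent_ion_mz Parent ion m/z in amu (same polarity as the run).
#' @param transformations Transformation table, see
#'   [default_biotransformations()]; must be non-empty with unique names.
#' @param tol Match tolerance in amu (> 0, inclusive).
#' @return data.frame with columns `id`, `mz`, `transformation`,
#'   `expected_mz`, `delta` (observed minus expected); zero rows when
#'   nothing matches.
#' @export
biotransformation_match <- function(features, parent_ion_mz,
                                    transformations =
                                      default_biotransformations(),
                                    tol = 0.01) {
  stopifnot(inherits(features, "feature_map"))
  if (is.null(transformations) || nrow(transformations) == 0L)
    stop("transformation list is empty", call. = FALSE)
  if (anyDuplicated(transformations$name))
    stop("transformation names must be unique", call. = FALSE)
  if (!is.finite(tol) || tol < 0) stop("tol must be >= 0", call. = FALSE)
  f <- features$features
  out <- list()
  for (k in seq_len(nrow(transformations))) {
    exp_mz <- parent_ion_mz + transformations$delta_mass[k]
    hit <- which(abs(f$mz - exp_mz) <= tol)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        id = f$id[hit], mz = f$mz[hit],
        transformation = transformations$name[k],
        expected_mz = exp_mz, delta = f$mz[hit] - exp_mz,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(id = character(0), mz = numeric(0),
                      transformation = character(0),
                      expected_mz = numeric(0), delta = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$mz, abs(res$delta)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mass defect filtering window
#'
#' @param half_width Half-width of the defect window in mDa (> 0); the
#'   window is centered on the parent's mass defect.
#' @param mass_range Two-element numeric, the neutral-mass range (amu) the
#'   filter considers.
#' @return A `mass_defect_window` list.
#' @export
mass_defect_window <- function(half_width = 40,
                               mass_range = c(100, 1000)) {
  if (!is.finite(half_width) || half_width <= 0)
    stop("half_width must be > 0", call. = FALSE)
  mass_range <- as.numeric(mass_range)
  if (length(mass_range) != 2L || mass_range[1] >= mass_range[2])
    stop("mass_range must be c(min, max) with min < max", call. = FALSE)
  structure(list(half_width = half_width, mass_range = mass_range),
            class = "mass_defect_window")
}

#' Mass defect filtering against a parent compound
#'
#' Converts each feature's ion m/z to a neutral monoisotopic mass using the
#' run polarity (proton correction, see [neutral_mass()]), then keeps the
#' feature when the neutral mass lies inside `window$mass_range` and the
#' absolute parent-relative mass defect ([mass_defect_from_parent()]) is at
#' most `window$half_width` mDa.
#'
#' @param features A `feature_map` (positive or negative polarity).
#' @param parent_mass Neutral monoisotopic mass of the parent drug in amu.
#' @param window A [mass_defect_window()].
#' @return data.frame of kept features with columns `id`, `mz`,
#'   `neutral_mass` and `defect_mda`.
#' @export
mass_defect_filter <- function(features, parent_mass,
                               window = mass_defect_window()) {
  stopifnot(inherits(features, "feature_map"),
            inherits(window, "mass_defect_window"))
  if (features$polarity == "neutral")
    stop("run polarity must be positive or negative", call. = FALSE)
  f <- features$features
  nm <- neutral_mass(f$mz, features$polarity)
  defect <- mass_defect_from_parent(nm, parent_mass)
  keep <- nm >= window$mass_range[1] & nm <= window$mass_range[2] &
    abs(defect) <= window$half_width
  out <- data.frame(id = f$id[keep], mz = f$mz[keep],
                    neutral_mass = nm[keep], defect_mda = defect[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
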