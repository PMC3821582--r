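#' Worked-example feature maps: pioglitazone and flurbiprofen microsome runs
#'
#' Feature maps transcribed from the published LC-TOF-MS twin-ion table for
#' the two model compounds: eight metabolite ion pairs for pioglitazone
#' (positive mode, d4 label, mass shift filtered at 4.00 +/- 0.04 amu) and
#' seven for flurbiprofen (negative mode, d3 label, 3.00 +/- 0.03 amu).
#' Intensities are base-peak-relative percentages as published.
#'
#' With `decoys = TRUE` each run additionally carries background ions that
#' violate exactly one filter criterion apiece - a shared matrix ion with
#' zero mass shift (also serving as the base peak of runs whose strongest
#' published ion is below 100 percent), a pair with the right co-elution but
#' a wrong mass shift, a pair with the right shift but a retention-time gap
#' beyond tolerance, and a pair with an intensity drift beyond 50 percent -
#' so that a correct filter returns exactly the published pairs.
#'
#' @param compound `"pioglitazone"` or `"flurbiprofen"`.
#' @param decoys Include the per-criterion decoy ions (default `TRUE`).
#' @return List with `unlabeled` and `labeled` `feature_map`s, plus
#'   `params`, the published [filter_params()] for the compound.
#' @examples
#' runs <- example_runs("flurbiprofen")
#' find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
#' @export
example_runs <- function(compound = c("pioglitazone", "flurbiprofen"),
                         decoys = TRUE) {
  compound <- match.arg(compound)
  if (compound == "pioglitazone") {
    u <- data.frame(
      rt = c(6.78, 7.46, 8.09, 8.12, 8.64, 9.89, 10.79, 11.66),
      mz = c(315.17, 389.11, 373.12, 272.13, 373.12, 373.12, 332.13,
             355.11),
      intensity = c(1.71, 10.83, 15.21, 2.01, 100.00, 11.96, 5.05, 1.35))
    l <- data.frame(
      rt = c(6.74, 7.44, 8.06, 8.09, 8.61, 9.85, 10.75, 11.57),
      mz = c(319.19, 393.14, 377.14, 276.15, 377.14, 377.14, 336.15,
             359.13),
      intensity = c(1.74, 6.59, 13.65, 1.89, 67.07, 7.07, 4.66, 1.28))
    polarity <- "positive"
    params <- filter_params(4.00, 0.04, 0.1, 0.5)
    shift <- 4.02
  } else {
    u <- data.frame(
      rt = c(9.26, 10.16, 11.50, 11.49, 11.50, 11.50, 11.97),
      mz = c(435.10, 275.07, 214.08, 229.06, 247.07, 259.07, 419.11),
      intensity = c(4.28, 5.30, 59.97, 20.50, 1.96, 7.17, 94.39))
    l <- data.frame(
      rt = c(9.24, 10.13, 11.46, 11.45, 11.46, 11.45, 11.94),
      mz = c(438.12, 278.08, 217.09, 232.08, 250.09, 262.09, 422.12),
      intensity = c(4.12, 4.94, 64.26, 18.76, 2.21, 7.01, 99.25))
    polarity <- "negative"
    params <- filter_params(3.00, 0.03, 0.1, 0.5)
    shift <- 3.02
  }
  u$id <- sprintf("%s_u%02d", substr(compound, 1, 3), seq_len(nrow(u)))
  l$id <- sprintf("%s_l%02d", substr(compound, 1, 3), seq_len(nrow(l)))
  if (decoys) {
    # one decoy per criterion; the shared matrix ion doubles as the base
    # peak so that published relative intensities are preserved
    matrix_ion <- data.frame(rt = 14.20, mz = 522.55, intensity = 100.00,
                             id = NA_character_)
    u_dec <- rbind(
      matrix_ion,
      data.frame(rt = 3.50, mz = 290.40, intensity = 30.00, id = NA),
      data.frame(rt = 4.60, mz = 310.22, intensity = 25.00, id = NA),
      data.frame(rt = 5.40, mz = 330.45, intensity = 40.00, id = NA),
      data.frame(rt = 2.50, mz = 450.33, intensity = 12.00, id = NA))
    # wrong shift (tolerance + 0.16), rt gap 0.30 min, drift -80 percent,
    # and one orphan ion per run with no counterpart at all
    l_dec <- rbind(
      matrix_ion,
      data.frame(rt = 3.48, mz = 290.40 + params$mass_shift +
                   params$mass_tol + 0.16, intensity = 29.00, id = NA),
      data.frame(rt = 4.30, mz = 310.22 + params$mass_shift,
                 intensity = 24.00, id = NA),
      data.frame(rt = 5.38, mz = 330.45 + params$mass_shift,
                 intensity = 8.00, id = NA),
      data.frame(rt = 13.10, mz = 610.77, intensity = 22.00, id = NA))
    u_dec$id <- sprintf("%s_udec%02d", substr(compound, 1, 3),
                        seq_len(nrow(u_dec)))
    l_dec$id <- sprintf("%s_ldec%02d", substr(compound, 1, 3),
                        seq_len(nrow(l_dec)))
    u <- rbind(u, u_dec)
    l <- rbind(l, l_dec)
  }
  list(
    unlabeled = feature_map(u, run_id = paste0(compound, "_unlabeled"),
                            polarity = polarity,
                            label_status = "unlabeled"),
    labeled = feature_map(l, run_id = paste0(compound, "_labeled"),
                          polarity = polarity, label_status = "labeled"),
    params = params,
    expected_shift = shift)
}

#' Worked-example accurate-mass ion table
#'
#' The published accurate masses and estimated ion formulas of the twin-ion
#' hits (un-labeled member), used by the formula-search and mass-defect
#' examples. `consistent` marks rows whose printed formula, formula mass and
#' ppm difference are mutually consistent under the standard monoisotopic
#' masses; the remaining rows carry typographical inconsistencies in the
#' original table and are kept for documentation, not asserted.
#'
#' @param compound `"pioglitazone"` or `"flurbiprofen"`.
#' @return data.frame with columns `rt`, `observed_mz`, `ion_formula`,
#'   `printed_ppm`, `consistent`.
#' @export
example_ion_table <- function(compound = c("pioglitazone",
                                           "flurbiprofen")) {
  compound <- match.arg(compound)
  if (compound == "pioglitazone") {
    data.frame(
      rt = c(6.78, 7.46, 8.09, 8.12, 8.64, 9.89, 10.79, 11.66),
      observed_mz = c(315.17012, 389.11569, 373.12111, 272.12734,
                      373.12123, 373.12106, 332.13076, 355.11028),
      ion_formula = c("C18H23N2O3", "C19H21N2O5S", "C19H21N2O4S",
                      "C16H18NO3", "C19H21N2O4S", "C19H21N2O4S",
                      "C18H22NO3S", "C22H15N2O3"),
      printed_ppm = c(0.63, 2.26, 1.46, 2.09, 1.14, 1.49, 2.22, 2.28),
      consistent = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      rt = c(9.26, 10.16, 11.50, 11.50, 11.50, 11.50, 11.97),
      observed_mz = c(435.10972, 275.07257, 214.07995, 229.06721,
                      247.07723, 259.07753, 419.11524),
      ion_formula = c("C21H20FO9", "C15H12FO4", NA, "C14H11FO2",
                      "C14H13FO2", "C15H12FO3", "C21H20FO8"),
      printed_ppm = c(-0.07, -0.21, NA, -0.79, 1.45, 0.26, -1.11),
      consistent = c(FALSE, FALSE, NA, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
}

#' Worked-example metabolite table (neutral formulas and mass defects)
#'
#' Published neutral formulas of the proposed metabolites with the
#' parent-relative mass defect (mDa). The parent row carries defect 0.
#'
#' @param compound `"pioglitazone"` or `"flurbiprofen"`.
#' @return data.frame with columns `metabolite`, `formula`, `printed_mass`,
#'   `printed_defect_mda`.
#' @export
example_metabolite_table <- function(compound = c("pioglitazone",
                                                  "flurbiprofen")) {
  compound <- match.arg(compound)
  if (compound == "pioglitazone") {
    data.frame(
      metabolite = c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8",
                     "parent"),
      formula = c("C18H22N2O3", "C19H20N2O5S", "C19H20N2O4S", "C16H17NO3",
                  "C19H20N2O4S", "C19H20N2O4S", "C18H21NO3S", "C22H14N2O3",
                  "C19H20N2O3S"),
      printed_mass = c(314.163043, 388.109295, 372.114380, 271.120844,
                       372.114380, 372.114380, 331.124216, 354.100443,
                       356.119465),
      printed_defect_mda = c(43.6, -10.2, -5.1, 1.4, -5.1, -5.1, 4.8,
                             -19.0, 0),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      metabolite = c("M1", "M2", "M3", "M4", "parent"),
      formula = c("C21H21FO9", "C15H13FO4", "C15H13FO3", "C21H21FO8",
                  "C15H13FO2"),
      printed_mass = c(436.116963, 276.079788, 260.084873, 420.122048,
                       244.089958),
      printed_defect_mda = c(27.0, -10.2, -5.1, 32.1, 0),
      stringsAsFactors = FALSE)
  }
}
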