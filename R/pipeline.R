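#' Read a pipeline configuration file
#'
#' YAML or JSON with one schema. Recognized keys: `unlabeled`, `labeled`
#' (feature-table paths), optional `reference_unlabeled` /
#' `reference_labeled` (compound-only runs for ion subtraction),
#' `polarity`; `filter` (mass_shift, mass_tol, rt_tol, intensity_drift);
#' optional `subtract` (mz_tol, rt_tol), `group` (rt_window),
#' `formula` (elements, ppm_tol), `out_dir`.
#'
#' @param path Config file (.yaml/.yml/.json).
#' @return Named list (validated by [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.cfg_get <- function(config, key, default = NULL, required = FALSE) {
  v <- config[[key]]
  if (is.null(v)) {
    if (required)
      stop("missing required config key '", key, "'", call. = FALSE)
    return(default)
  }
  v
}

#' Run the full mass-shift filtering pipeline
#'
#' Stages: read the two feature tables, optionally subtract
#' compound-specific reference ions, extract twin pairs, group co-eluting
#' hits, enumerate candidate formulas for each distinct un-labeled hit m/z,
#' and write pair/group/formula tables plus a stage-count summary to the
#' output directory. Deterministic given inputs and config; an empty result
#' is not an error.
#'
#' @param config Named list (see [read_pipeline_config()]) or a path to a
#'   config file.
#' @param verbose Log stage counts to stderr.
#' @return Invisibly, a list with `pairs`, `groups`, `formulas` and
#'   `summary` (named integer vector of per-stage counts).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  polarity <- .cfg_get(config, "polarity", "positive")
  upath <- .cfg_get(config, "unlabeled", required = TRUE)
  lpath <- .cfg_get(config, "labeled", required = TRUE)
  unlabeled <- read_feature_table(upath, polarity = polarity,
                                  label_status = "unlabeled")
  labeled <- read_feature_table(lpath, polarity = polarity,
                                label_status = "labeled")
  say("loaded %d unlabeled / %d labeled features",
      nrow(unlabeled$features), nrow(labeled$features))

  sub <- .cfg_get(config, "subtract", list())
  for (role in c("unlabeled", "labeled")) {
    rp <- .cfg_get(config, paste0("reference_", role))
    if (!is.null(rp)) {
      ref <- read_feature_table(rp, polarity = polarity,
                                label_status = role)
      before <- nrow(get(role)$features)
      assign(role, subtract_reference_ions(
        get(role), ref,
        mz_tol = .cfg_get(sub, "mz_tol", 0.01),
        rt_tol = .cfg_get(sub, "rt_tol", 0.1)))
      say("reference subtraction (%s): %d -> %d features", role, before,
          nrow(get(role)$features))
    }
  }

  fcfg <- .cfg_get(config, "filter", required = TRUE)
  params <- filter_params(
    mass_shift = .cfg_get(fcfg, "mass_shift", required = TRUE),
    mass_tol = .cfg_get(fcfg, "mass_tol", required = TRUE),
    rt_tol = .cfg_get(fcfg, "rt_tol", 0.1),
    intensity_drift = .cfg_get(fcfg, "intensity_drift", 0.5))
  pairs <- find_twin_pairs(unlabeled, labeled, params)
  say("twin pairs: %d", nrow(pairs))

  gcfg <- .cfg_get(config, "group", list())
  groups <- group_coeluting(pairs,
                            rt_window = .cfg_get(gcfg, "rt_window", 0.05))
  say("metabolite groups: %d", length(groups))

  fscfg <- .cfg_get(config, "formula", list())
  bounds <- .cfg_get(fscfg, "elements")
  bounds <- if (is.null(bounds)) element_bounds()
            else parse_element_bounds(bounds)
  ppm_tol <- .cfg_get(fscfg, "ppm_tol", 5)
  hit_mz <- unique(round(pairs$mz_unlabeled, 5))
  formulas <- if (length(hit_mz)) {
    do.call(rbind, lapply(hit_mz, function(mz) {
      cand <- enumerate_formulas(mz, polarity, bounds, ppm_tol)
      if (nrow(cand)) cbind(observed_mz = mz,
                            cand[seq_len(min(5L, nrow(cand))), ,
                                 drop = FALSE])
      else NULL
    }))
  } else NULL
  if (is.null(formulas))
    formulas <- data.frame(observed_mz = numeric(0), formula = character(0),
                           theoretical_mz = numeric(0), ppm = numeric(0),
                           rdbe = numeric(0), stringsAsFactors = FALSE)
  say("formula candidates: %d (for %d distinct m/z)", nrow(formulas),
      length(hit_mz))

  summary <- c(unlabeled_features = nrow(unlabeled$features),
               labeled_features = nrow(labeled$features),
               twin_pairs = nrow(pairs),
               metabolite_groups = length(groups),
               formula_candidates = nrow(formulas))

  out_dir <- .cfg_get(config, "out_dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(pairs),
                       file.path(out_dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report_pairs(pairs),
                       file.path(out_dir, "pairs_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gdf <- if (length(groups)) do.call(rbind, lapply(seq_along(groups),
      function(i) {
        g <- groups[[i]]
        data.frame(group = i, rt_center = g$rt_center,
                   precursor_mz = g$precursor_mz,
                   n_ions = nrow(g$pairs),
                   member_mz = paste(sprintf("%.4f", g$pairs$mz_unlabeled),
                                     collapse = ";"),
                   stringsAsFactors = FALSE)
      })) else data.frame(group = integer(0), rt_center = numeric(0),
                          precursor_mz = numeric(0), n_ions = integer(0),
                          member_mz = character(0))
    utils::write.table(gdf, file.path(out_dir, "groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(formulas, file.path(out_dir, "formulas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(summary), summary, sep = "\t"),
               file.path(out_dir, "summary.tsv"))
  }
  invisible(list(pairs = pairs, groups = groups, formulas = formulas,
                 summary = summary))
}
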