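#' Twin-ion filter parameters
#'
#' The filter keeps a pair of features (un-labeled, labeled) when all three
#' conditions hold, with inclusive bounds:
#' \itemize{
#'   \item mass shift: |(mz_labeled - mz_unlabeled) - mass_shift| <= mass_tol
#'   \item co-elution: |rt_labeled - rt_unlabeled| <= rt_tol
#'   \item intensity drift: |(I_labeled - I_unlabeled)/I_unlabeled| <=
#'     intensity_drift, evaluated by default on base-peak-relative
#'     intensities.
#' }
#'
#' @param mass_shift Expected label mass shift in amu (> 0), e.g. 4.00 for a
#'   d4 label filtered at 4.00 +/- 0.04.
#' @param mass_tol Mass-shift tolerance in amu (> 0).
#' @param rt_tol Retention-time tolerance in minutes (>= 0); default 0.1.
#' @param intensity_drift Allowed relative intensity drift as a fraction
#'   (default 0.5, i.e. +/- 50 percent).
#' @param intensity_mode `"relative"` (drift on base-peak-relative
#'   intensities, the default) or `"raw"`.
#' @param require_intensity If `FALSE` the intensity criterion is skipped
#'   (used to study background at relaxed settings).
#' @return A `filter_params` list.
#' @export
filter_params <- function(mass_shift, mass_tol, rt_tol = 0.1,
                          intensity_drift = 0.5,
                          intensity_mode = c("relative", "raw"),
                          require_intensity = TRUE) {
  intensity_mode <- match.arg(intensity_mode)
  if (!is.finite(mass_shift) || mass_shift <= 0)
    stop("mass_shift must be > 0", call. = FALSE)
  if (!is.finite(mass_tol) || mass_tol <= 0)
    stop("mass_tol must be > 0", call. = FALSE)
  if (rt_tol < 0) stop("rt_tol must be >= 0", call. = FALSE)
  if (intensity_drift < 0) stop("intensity_drift must be >= 0",
                                call. = FALSE)
  structure(list(mass_shift = mass_shift, mass_tol = mass_tol,
                 rt_tol = rt_tol, intensity_drift = intensity_drift,
                 intensity_mode = intensity_mode,
                 require_intensity = isTRUE(require_intensity)),
            class = "filter_params")
}

# intensities used by the drift criterion for one map
.filter_intensities <- function(map, mode) {
  ints <- map$features$intensity
  if (mode == "relative" && length(ints)) 100 * ints / max(ints) else ints
}

# assemble the twin-pair data.frame for index vectors iu (unlabeled rows)
# and il (labeled rows)
.twin_rows <- function(fu, fl, relu, rell, iu, il) {
  data.frame(
    id_unlabeled = fu$id[iu], id_labeled = fl$id[il],
    rt_unlabeled = fu$rt[iu], rt_labeled = fl$rt[il],
    mz_unlabeled = fu$mz[iu], mz_labeled = fl$mz[il],
    rel_intensity_unlabeled = relu[iu], rel_intensity_labeled = rell[il],
    delta_rt = fl$rt[il] - fu$rt[iu],
    delta_mz = fl$mz[il] - fu$mz[iu],
    delta_intensity_pct = (rell[il] - relu[iu]) / relu[iu] * 100,
    stringsAsFactors = FALSE)
}

# core pairing used by both the two-run and mixture entry points.
# candidates: data.frame of index pairs already satisfying the criteria.
.resolve_pairs <- function(cand, fu, fl, relu, rell, params) {
  if (nrow(cand) == 0L) {
    out <- .twin_rows(fu, fl, relu, rell, integer(0), integer(0))
  } else {
    d <- abs((fl$mz[cand$il] - fu$mz[cand$iu]) - params$mass_shift) /
      params$mass_tol +
      abs(fl$rt[cand$il] - fu$rt[cand$iu]) /
      max(params$rt_tol, .Machine$double.eps)
    o <- order(d, fl$mz[cand$il], fu$mz[cand$iu], fu$rt[cand$iu])
    tu <- rep(FALSE, nrow(fu)); tl <- rep(FALSE, nrow(fl))
    keep <- integer(0)
    for (k in o) {
      if (tu[cand$iu[k]] || tl[cand$il[k]]) next
      tu[cand$iu[k]] <- TRUE; tl[cand$il[k]] <- TRUE
      keep <- c(keep, k)
    }
    out <- .twin_rows(fu, fl, relu, rell, cand$iu[keep], cand$il[keep])
    out <- out[order(out$rt_unlabeled, out$mz_unlabeled), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.twin_candidates <- function(fu, fl, relu, rell, params, exclude_self) {
  if (nrow(fu) == 0L || nrow(fl) == 0L)
    return(data.frame(iu = integer(0), il = integer(0)))
  dmz <- outer(fu$mz, fl$mz, function(u, l) l - u)
  ok <- abs(dmz - params$mass_shift) <= params$mass_tol &
    outer(fu$rt, fl$rt, function(u, l) abs(l - u)) <= params$rt_tol
  if (params$require_intensity) {
    drift <- outer(relu, rell, function(u, l) abs((l - u) / u))
    ok <- ok & drift <= params$intensity_drift
  }
  if (exclude_self) diag(ok) <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  data.frame(iu = idx[, 1], il = idx[, 2])
}

#' Extract twin-ion pairs between an un-labeled and a labeled run
#'
#' The core mass-shift filter: every cross-run pair of features satisfying
#' the mass-shift, retention-time and intensity-drift criteria of
#' [filter_params()] becomes a candidate; candidates are resolved one-to-one
#' (no feature appears in two pairs) greedily by the normalized distance
#' |delta_mz - mass_shift|/mass_tol + |delta_rt|/rt_tol, ties broken on the
#' lower labeled m/z. Reported deltas follow the conventions
#' delta_rt = rt(labeled) - rt(unlabeled),
#' delta_mz = mz(labeled) - mz(unlabeled), and
#' delta_intensity_pct = (labeled - unlabeled)/unlabeled * 100 on base-peak-
#' relative intensities.
#'
#' @param unlabeled `feature_map` with `label_status == "unlabeled"`.
#' @param labeled `feature_map` with `label_status == "labeled"`.
#' @param params A [filter_params()] object.
#' @return A `twin_pairs` object: data.frame of pairs sorted by un-labeled
#'   rt then m/z, with the filter parameters as attribute `params`.
#' @examples
#' runs <- example_runs("pioglitazone")
#' find_twin_pairs(runs$unlabeled, runs$labeled,
#'                 filter_params(4.00, 0.04, 0.1, 0.5))
#' @export
find_twin_pairs <- function(unlabeled, labeled, params) {
  stopifnot(inherits(unlabeled, "feature_map"),
            inherits(labeled, "feature_map"),
            inherits(params, "filter_params"))
  if (unlabeled$label_status != "unlabeled")
    stop("first map must have label_status 'unlabeled'", call. = FALSE)
  if (labeled$label_status != "labeled")
    stop("second map must have label_status 'labeled'", call. = FALSE)
  if (unlabeled$polarity != labeled$polarity)
    stop("runs have different polarity", call. = FALSE)
  fu <- unlabeled$features; fl <- labeled$features
  relu <- .filter_intensities(unlabeled, params$intensity_mode)
  rell <- .filter_intensities(labeled, params$intensity_mode)
  cand <- .twin_candidates(fu, fl, relu, rell, params, exclude_self = FALSE)
  out <- .resolve_pairs(cand, fu, fl, relu, rell, params)
  structure(out, params = params, class = c("twin_pairs", "data.frame"))
}

#' Extract twin-ion pairs within a single mixture run
#'
#' For a run of mixed labeled and un-labeled material, pairs are formed
#' within the one map: for every ordered pair of distinct features, the
#' lower-m/z member is treated as the un-labeled ion (the true un-labeled
#' ion is always lighter by the label mass). Tolerance semantics and
#' conflict resolution match [find_twin_pairs()]; a feature participates in
#' at most one pair.
#'
#' @param mixture `feature_map` with `label_status == "mixture"`.
#' @param params A [filter_params()] object.
#' @return A `twin_pairs` object.
#' @export
find_twin_pairs_mixture <- function(mixture, params) {
  stopifnot(inherits(mixture, "feature_map"),
            inherits(params, "filter_params"))
  if (mixture$label_status != "mixture")
    stop("map must have label_status 'mixture'", call. = FALSE)
  f <- mixture$features
  rel <- .filter_intensities(mixture, params$intensity_mode)
  cand <- .twin_candidates(f, f, rel, rel, params, exclude_self = TRUE)
  # one-to-one across roles: a feature used as unlabeled cannot also be the
  # labeled member of another pair, so resolve on a single "taken" set
  if (nrow(cand)) {
    d <- abs((f$mz[cand$il] - f$mz[cand$iu]) - params$mass_shift) /
      params$mass_tol +
      abs(f$rt[cand$il] - f$rt[cand$iu]) /
      max(params$rt_tol, .Machine$double.eps)
    o <- order(d, f$mz[cand$il], f$mz[cand$iu], f$rt[cand$iu])
    taken <- rep(FALSE, nrow(f))
    keep <- integer(0)
    for (k in o) {
      if (taken[cand$iu[k]] || taken[cand$il[k]]) next
      taken[cand$iu[k]] <- TRUE; taken[cand$il[k]] <- TRUE
      keep <- c(keep, k)
    }
    cand <- cand[keep, , drop = FALSE]
  }
  out <- .twin_rows(f, f, rel, rel, cand$iu, cand$il)
  out <- out[order(out$rt_unlabeled, out$mz_unlabeled), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = params, class = c("twin_pairs", "data.frame"))
}

#' @export
print.twin_pairs <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(paste0("<twin_pairs> %d pair(s) at mass shift %.2f +/- %.2f ",
                     "amu, rt +/- %.2f min, drift +/- %.0f%%\n"),
              nrow(x), p$mass_shift, p$mass_tol, p$rt_tol,
              100 * p$intensity_drift))
  if (nrow(x)) print(report_pairs(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.twin_pairs <- function(object, ...) {
  cat(sprintf("twin pairs: %d\n", nrow(object)))
  if (nrow(object)) {
    cat(sprintf("  rt range (unlabeled): %.2f-%.2f min\n",
                min(object$rt_unlabeled), max(object$rt_unlabeled)))
    cat(sprintf("  delta rt: %.3f to %.3f min (labeled minus unlabeled)\n",
                min(object$delta_rt), max(object$delta_rt)))
    cat(sprintf("  delta m/z: %.4f to %.4f amu\n",
                min(object$delta_mz), max(object$delta_mz)))
    cat(sprintf("  intensity drift: %.0f%% to %.0f%%\n",
                min(object$delta_intensity_pct),
                max(object$delta_intensity_pct)))
  }
  invisible(object)
}

#' Plot twin pairs in the retention time-m/z plane
#'
#' Simple static map view: un-labeled members in red, labeled in blue,
#' matched pairs joined and circled.
#'
#' @param x A `twin_pairs` object.
#' @param maps Optional list of the two `feature_map`s to show as background.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.twin_pairs <- function(x, maps = NULL, ...) {
  xs <- c(x$rt_unlabeled, x$rt_labeled)
  ys <- c(x$mz_unlabeled, x$mz_labeled)
  if (!is.null(maps)) {
    for (m in maps) {
      xs <- c(xs, m$features$rt); ys <- c(ys, m$features$mz)
    }
  }
  graphics::plot(xs, ys, type = "n", xlab = "retention time (min)",
                 ylab = "m/z (amu)", ...)
  if (!is.null(maps)) {
    cols <- c("#D55E0055", "#0072B255")
    for (i in seq_along(maps))
      graphics::points(maps[[i]]$features$rt, maps[[i]]$features$mz,
                       pch = 16, col = cols[(i - 1L) %% 2L + 1L])
  }
  graphics::segments(x$rt_unlabeled, x$mz_unlabeled, x$rt_labeled,
                     x$mz_labeled, col = "grey40")
  graphics::points(x$rt_unlabeled, x$mz_unlabeled, pch = 16, col = "red")
  graphics::points(x$rt_labeled, x$mz_labeled, pch = 16, col = "blue")
  graphics::points((x$rt_unlabeled + x$rt_labeled) / 2,
                   (x$mz_unlabeled + x$mz_labeled) / 2, pch = 1, cex = 3)
  invisible(x)
}

#' Group co-eluting twin pairs into metabolite groups
#'
#' Single-linkage clustering of pairs on un-labeled retention time with
#' linkage distance `rt_window`. Within each group the precursor is the
#' member with the largest un-labeled m/z; the remaining members are
#' candidate in-source fragments. When a neutral-loss table is supplied
#' (`split_unmatched = TRUE`), members whose m/z difference from the
#' precursor matches no table entry within `loss_tol` are split off into
#' their own groups: co-elution alone does not make an ion a fragment of
#' the precursor.
#'
#' @param pairs A `twin_pairs` object.
#' @param rt_window Co-elution window in minutes (>= 0); default 0.05.
#' @param losses Optional neutral-loss table, see [default_neutral_losses()].
#' @param loss_tol Loss-match tolerance in amu; default 0.01.
#' @param split_unmatched Split off members with no matching loss.
#' @return A `metabolite_groups` object: list of groups ordered by rt
#'   center, each with elements `pairs` (the member rows), `rt_center`,
#'   `precursor_mz`, `precursor_id` and `fragment_annotations`.
#' @export
group_coeluting <- function(pairs, rt_window = 0.05, losses = NULL,
                            loss_tol = 0.01, split_unmatched = !is.null(losses)) {
  stopifnot(inherits(pairs, "twin_pairs") || is.data.frame(pairs))
  if (rt_window < 0) stop("rt_window must be >= 0", call. = FALSE)
  if (nrow(pairs) == 0L)
    return(structure(list(), class = "metabolite_groups"))
  o <- order(pairs$rt_unlabeled, pairs$mz_unlabeled)
  p <- pairs[o, , drop = FALSE]
  # single linkage on sorted rt: a gap > rt_window starts a new cluster
  gaps <- diff(p$rt_unlabeled) > rt_window
  cluster <- cumsum(c(0L, as.integer(gaps)))
  groups <- lapply(split(seq_len(nrow(p)), cluster), function(ii) {
    p[ii, , drop = FALSE]
  })
  if (isTRUE(split_unmatched) && !is.null(losses)) {
    groups <- unlist(lapply(groups, function(g) {
      if (nrow(g) <= 1L) return(list(g))
      prec <- which.max(g$mz_unlabeled)
      loss <- g$mz_unlabeled[prec] - g$mz_unlabeled
      matched <- vapply(loss, function(x) {
        x == 0 || any(abs(losses$mass - x) <= loss_tol)
      }, logical(1))
      out <- list(g[matched, , drop = FALSE])
      for (i in which(!matched)) out <- c(out, list(g[i, , drop = FALSE]))
      out
    }), recursive = FALSE)
  }
  groups <- lapply(groups, function(g) {
    prec <- which.max(g$mz_unlabeled)
    grp <- list(pairs = g,
                rt_center = mean(g$rt_unlabeled),
                precursor_id = g$id_unlabeled[prec],
                precursor_mz = g$mz_unlabeled[prec],
                fragment_annotations = NULL)
    class(grp) <- "metabolite_group"
    grp
  })
  groups <- groups[order(vapply(groups, `[[`, numeric(1), "rt_center"))]
  structure(unname(groups), class = "metabolite_groups")
}

#' @export
print.metabolite_groups <- function(x, ...) {
  cat(sprintf("<metabolite_groups> %d group(s)\n", length(x)))
  for (i in seq_along(x)) {
    g <- x[[i]]
    cat(sprintf("  group %d: rt %.2f min, %d ion(s), precursor m/z %.2f\n",
                i, g$rt_center, nrow(g$pairs), g$precursor_mz))
    if (!is.null(g$fragment_annotations) && nrow(g$fragment_annotations))
      for (j in seq_len(nrow(g$fragment_annotations)))
        cat(sprintf("    fragment m/z %.2f: loss %.5f amu (%s)\n",
                    g$fragment_annotations$mz[j],
                    g$fragment_annotations$loss_mass[j],
                    g$fragment_annotations$label[j]))
  }
  invisible(x)
}

#' Default neutral-loss table for in-source fragment annotation
#'
#' Common small neutral losses with mass-correct labels. The loss mass is
#' the m/z difference between the intact precursor ion and the in-source
#' fragment ion.
#'
#' @return data.frame with columns `label` and `mass` (amu).
#' @export
default_neutral_losses <- function() {
  data.frame(
    label = c("C", "CH2", "CH4", "NH3", "H2O", "C2H2", "CO", "CH2O",
              "CH3OH", "CO2", "CO2H", "HCOOH", "C2H4O2", "SO2", "SO3",
              "C6H8O6"),
    mass = c(12.0, 14.015650, 16.031300, 17.026549, 18.010565, 26.015650,
             27.994915, 30.010565, 32.026215, 43.989830, 44.997654,
             46.005479, 60.021129, 63.961901, 79.956815, 176.032088),
    stringsAsFactors = FALSE)
}

#' Annotate in-source fragments of a metabolite group by neutral loss
#'
#' For each non-precursor member, the loss mass is the precursor m/z minus
#' the member m/z; the closest loss-table entry within `tol` provides the
#' label, otherwise the member is reported as `"unassigned"`.
#'
#' @param group A `metabolite_group` (element of [group_coeluting()] output).
#' @param losses Loss table, see [default_neutral_losses()].
#' @param tol Match tolerance in amu.
#' @return The group with `fragment_annotations` filled in (data.frame with
#'   columns `id`, `mz`, `loss_mass`, `label`).
#' @export
annotate_neutral_losses <- function(group, losses = default_neutral_losses(),
                                    tol = 0.01) {
  stopifnot(inherits(group, "metabolite_group"))
  g <- group$pairs
  if (nrow(g) == 0L) stop("empty metabolite group", call. = FALSE)
  others <- which(g$id_unlabeled != group$precursor_id)
  if (length(others) == 0L) {
    group$fragment_annotations <- data.frame(
      id = character(0), mz = numeric(0), loss_mass = numeric(0),
      label = character(0), stringsAsFactors = FALSE)
    return(group)
  }
  loss <- group$precursor_mz - g$mz_unlabeled[others]
  lab <- vapply(loss, function(x) {
    d <- abs(losses$mass - x)
    i <- which.min(d)
    if (length(i) && d[i] <= tol) losses$label[i] else "unassigned"
  }, character(1))
  group$fragment_annotations <- data.frame(
    id = g$id_unlabeled[others], mz = g$mz_unlabeled[others],
    loss_mass = loss, label = lab, stringsAsFactors = FALSE)
  group
}

#' Report twin pairs in the two-line table layout
#'
#' One two-line block per pair: the first line is the un-labeled ion
#' (rt, relative intensity, m/z), the second the labeled ion plus the
#' deltas. Rounding: rt and relative intensity 2 dp, delta rt 2 dp,
#' delta intensity integer percent, m/z 2 dp, delta m/z 2 dp with a "+"
#' prefix. Filtering itself always uses unrounded values.
#'
#' @param pairs A `twin_pairs` object.
#' @return data.frame with character columns `rt`, `delta_rt`,
#'   `intensity_pct`, `delta_intensity_pct`, `mz`, `delta_mz`; rows
#'   alternate un-labeled / labeled.
#' @export
report_pairs <- function(pairs) {
  stopifnot(inherits(pairs, "twin_pairs") || is.data.frame(pairs))
  n <- nrow(pairs)
  out <- data.frame(pair = integer(2 * n), rt = character(2 * n),
                    delta_rt = character(2 * n),
                    intensity_pct = character(2 * n),
                    delta_intensity_pct = character(2 * n),
                    mz = character(2 * n), delta_mz = character(2 * n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    u <- 2L * i - 1L; l <- 2L * i
    out$pair[u] <- i; out$pair[l] <- i
    out$rt[u] <- sprintf("%.2f", pairs$rt_unlabeled[i])
    out$rt[l] <- sprintf("%.2f", pairs$rt_labeled[i])
    out$delta_rt[u] <- ""
    out$delta_rt[l] <- sprintf("%.2f", pairs$delta_rt[i])
    out$intensity_pct[u] <- sprintf("%.2f", pairs$rel_intensity_unlabeled[i])
    out$intensity_pct[l] <- sprintf("%.2f", pairs$rel_intensity_labeled[i])
    out$delta_intensity_pct[u] <- ""
    out$delta_intensity_pct[l] <-
      sprintf("%d", as.integer(round(pairs$delta_intensity_pct[i])))
    out$mz[u] <- sprintf("%.2f", pairs$mz_unlabeled[i])
    out$mz[l] <- sprintf("%.2f", pairs$mz_labeled[i])
    out$delta_mz[u] <- ""
    out$delta_mz[l] <- sprintf("+%.2f", pairs$delta_mz[i])
  }
  out
}
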