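#' Feature detection parameters
#'
#' @param mz_tol Centroid linkage tolerance in amu (> 0). Consecutive-scan
#'   centroids within this tolerance are chained into one trace.
#' @param min_scans Minimum trace length in scans (>= 1).
#' @param min_intensity Minimum apex intensity; weaker traces are dropped.
#' @param rt_gap_max Maximum retention-time gap (minutes) a trace may skip
#'   before it is closed.
#' @return A `detection_params` list.
#' @export
detection_params <- function(mz_tol = 0.02, min_scans = 3L,
                             min_intensity = 0, rt_gap_max = 0.05) {
  if (!is.finite(mz_tol) || mz_tol <= 0) stop("mz_tol must be > 0",
                                              call. = FALSE)
  if (min_scans < 1L) stop("min_scans must be >= 1", call. = FALSE)
  if (rt_gap_max < 0) stop("rt_gap_max must be >= 0", call. = FALSE)
  structure(list(mz_tol = mz_tol, min_scans = as.integer(min_scans),
                 min_intensity = min_intensity, rt_gap_max = rt_gap_max),
            class = "detection_params")
}

#' Detect features from centroided scans
#'
#' Centroids are chained scan-to-scan into chromatographic traces: a centroid
#' extends an open trace when its m/z is within `mz_tol` of the trace's
#' running intensity-weighted mean m/z and the time gap since the trace's
#' last scan is at most `rt_gap_max`. Traces shorter than `min_scans` or with
#' an apex below `min_intensity` are dropped. Each feature reports the apex
#' scan time as rt, the apex intensity, and the intensity-weighted mean m/z
#' of its trace.
#'
#' @param scans List of `centroid_scan`, sorted by scan time.
#' @param params A [detection_params()] object.
#' @param run_id,polarity,label_status Metadata for the output map.
#' @return A `feature_map`, features sorted by rt then m/z.
#' @export
detect_features <- function(scans, params = detection_params(),
                            run_id = "run",
                            polarity = c("positive", "negative", "neutral"),
                            label_status = c("unlabeled", "labeled",
                                             "mixture")) {
  polarity <- match.arg(polarity)
  label_status <- match.arg(label_status)
  stopifnot(inherits(params, "detection_params"))
  if (length(scans) == 0L)
    return(feature_map(NULL, run_id, polarity, label_status))
  times <- vapply(scans, `[[`, numeric(1), "scan_time")
  if (is.unsorted(times)) stop("scans must be sorted by scan_time",
                               call. = FALSE)

  # open traces: running sums for weighted m/z plus apex bookkeeping
  open <- list()   # each: list(mzw, w, last_time, n, apex_int, apex_rt)
  done <- list()
  for (si in seq_along(scans)) {
    sc <- scans[[si]]
    t <- sc$scan_time
    # close traces that have gapped out
    if (length(open)) {
      lt <- vapply(open, `[[`, numeric(1), "last_time")
      expired <- which(t - lt > params$rt_gap_max & lt < t)
      if (length(expired)) {
        done <- c(done, open[expired])
        open <- open[-expired]
      }
    }
    if (length(sc$mz) == 0L) next
    used <- rep(FALSE, length(sc$mz))
    if (length(open)) {
      trace_mz <- vapply(open, function(tr) tr$mzw / tr$w, numeric(1))
      # assign centroids to traces greedily by m/z distance
      cand <- which(outer(sc$mz, trace_mz,
                          function(a, b) abs(a - b)) <= params$mz_tol,
                    arr.ind = TRUE)
      if (nrow(cand)) {
        d <- abs(sc$mz[cand[, 1]] - trace_mz[cand[, 2]])
        o <- order(d, sc$mz[cand[, 1]])
        taken_tr <- rep(FALSE, length(open))
        for (k in o) {
          ci <- cand[k, 1]; ti <- cand[k, 2]
          if (used[ci] || taken_tr[ti]) next
          used[ci] <- TRUE; taken_tr[ti] <- TRUE
          tr <- open[[ti]]
          tr$mzw <- tr$mzw + sc$mz[ci] * sc$intensity[ci]
          tr$w <- tr$w + sc$intensity[ci]
          tr$last_time <- t
          tr$n <- tr$n + 1L
          if (sc$intensity[ci] > tr$apex_int) {
            tr$apex_int <- sc$intensity[ci]
            tr$apex_rt <- t
          }
          open[[ti]] <- tr
        }
      }
    }
    for (ci in which(!used)) {
      open[[length(open) + 1L]] <- list(
        mzw = sc$mz[ci] * sc$intensity[ci], w = sc$intensity[ci],
        last_time = t, n = 1L, apex_int = sc$intensity[ci], apex_rt = t)
    }
  }
  done <- c(done, open)
  if (length(done) == 0L)
    return(feature_map(NULL, run_id, polarity, label_status))
  keep <- vapply(done, function(tr) {
    tr$n >= params$min_scans && tr$apex_int >= params$min_intensity
  }, logical(1))
  done <- done[keep]
  if (length(done) == 0L)
    return(feature_map(NULL, run_id, polarity, label_status))
  df <- data.frame(
    rt = vapply(done, `[[`, numeric(1), "apex_rt"),
    mz = vapply(done, function(tr) tr$mzw / tr$w, numeric(1)),
    intensity = vapply(done, `[[`, numeric(1), "apex_int"),
    stringsAsFactors = FALSE)
  df <- df[order(df$rt, df$mz), , drop = FALSE]
  feature_map(df, run_id, polarity, label_status)
}

#' Align the features of two runs
#'
#' Greedy one-to-one nearest-neighbour matching on the normalized distance
#' d = |rt_a - rt_b| / rt_tol + |mz_a - mz_b| / mz_tol over all cross-run
#' candidates within both tolerances (inclusive). Ties break on lower m/z,
#' then earlier rt, of the first run's feature. Unmatched features of either
#' run are reported with an absent partner.
#'
#' @param a,b `feature_map`s of the same polarity.
#' @param rt_tol Retention-time tolerance in minutes.
#' @param mz_tol m/z tolerance in amu.
#' @return data.frame with columns `id_a`, `id_b` (NA when unmatched),
#'   `rt_a`, `rt_b`, `mz_a`, `mz_b`, `rt_offset` (rt_b - rt_a).
#' @export
align_runs <- function(a, b, rt_tol = 0.1, mz_tol = 0.01) {
  stopifnot(inherits(a, "feature_map"), inherits(b, "feature_map"))
  if (a$polarity != b$polarity)
    stop("cannot align runs of different polarity", call. = FALSE)
  fa <- a$features; fb <- b$features
  na_ <- nrow(fa); nb <- nrow(fb)
  match_b <- rep(NA_integer_, na_)
  if (na_ && nb) {
    cand <- which(outer(fa$rt, fb$rt, function(x, y) abs(x - y)) <= rt_tol &
                  outer(fa$mz, fb$mz, function(x, y) abs(x - y)) <= mz_tol,
                  arr.ind = TRUE)
    if (nrow(cand)) {
      ia <- cand[, 1]; ib <- cand[, 2]
      d <- abs(fa$rt[ia] - fb$rt[ib]) / max(rt_tol, .Machine$double.eps) +
        abs(fa$mz[ia] - fb$mz[ib]) / mz_tol
      o <- order(d, fa$mz[ia], fa$rt[ia], fb$mz[ib])
      ta <- rep(FALSE, na_); tb <- rep(FALSE, nb)
      for (k in o) {
        if (ta[ia[k]] || tb[ib[k]]) next
        ta[ia[k]] <- TRUE; tb[ib[k]] <- TRUE
        match_b[ia[k]] <- ib[k]
      }
    }
  }
  rows_a <- data.frame(
    id_a = if (na_) fa$id else character(0),
    id_b = if (na_) ifelse(is.na(match_b), NA_character_,
                           fb$id[match_b]) else character(0),
    rt_a = fa$rt, rt_b = if (na_) fb$rt[match_b] else numeric(0),
    mz_a = fa$mz, mz_b = if (na_) fb$mz[match_b] else numeric(0),
    stringsAsFactors = FALSE)
  orphan_b <- if (nb) setdiff(seq_len(nb), match_b[!is.na(match_b)])
              else integer(0)
  if (length(orphan_b)) {
    rows_b <- data.frame(id_a = NA_character_, id_b = fb$id[orphan_b],
                         rt_a = NA_real_, rt_b = fb$rt[orphan_b],
                         mz_a = NA_real_, mz_b = fb$mz[orphan_b],
                         stringsAsFactors = FALSE)
    rows_a <- rbind(rows_a, rows_b)
  }
  rows_a$rt_offset <- rows_a$rt_b - rows_a$rt_a
  rownames(rows_a) <- NULL
  rows_a
}
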