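# Independent brute-force oracles, written from the definitions (plain
# loops), used to cross-check the package implementations on small inputs.

# all cross-run pairs passing the three criteria, then the same one-to-one
# conflict-resolution rule (ascending normalized distance, ties on lower
# labeled m/z), coded independently with explicit loops
oracle_twin_pairs <- function(unlabeled, labeled, params) {
  fu <- unlabeled$features
  fl <- labeled$features
  relu <- if (nrow(fu)) 100 * fu$intensity / max(fu$intensity) else numeric(0)
  rell <- if (nrow(fl)) 100 * fl$intensity / max(fl$intensity) else numeric(0)
  cand <- list()
  for (i in seq_len(nrow(fu))) {
    for (j in seq_len(nrow(fl))) {
      dmz <- fl$mz[j] - fu$mz[i]
      drt <- fl$rt[j] - fu$rt[i]
      dint <- (rell[j] - relu[i]) / relu[i]
      if (abs(dmz - params$mass_shift) <= params$mass_tol &&
          abs(drt) <= params$rt_tol &&
          (!params$require_intensity ||
             abs(dint) <= params$intensity_drift)) {
        d <- abs(dmz - params$mass_shift) / params$mass_tol +
          abs(drt) / max(params$rt_tol, .Machine$double.eps)
        cand[[length(cand) + 1L]] <- list(i = i, j = j, d = d,
                                          mzl = fl$mz[j], mzu = fu$mz[i],
                                          rtu = fu$rt[i])
      }
    }
  }
  if (length(cand) == 0L)
    return(data.frame(id_unlabeled = character(0),
                      id_labeled = character(0)))
  ord <- order(vapply(cand, `[[`, numeric(1), "d"),
               vapply(cand, `[[`, numeric(1), "mzl"),
               vapply(cand, `[[`, numeric(1), "mzu"),
               vapply(cand, `[[`, numeric(1), "rtu"))
  used_u <- logical(nrow(fu)); used_l <- logical(nrow(fl))
  rows <- list()
  for (k in ord) {
    ci <- cand[[k]]
    if (used_u[ci$i] || used_l[ci$j]) next
    used_u[ci$i] <- TRUE; used_l[ci$j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      id_unlabeled = fu$id[ci$i], id_labeled = fl$id[ci$j],
      rt_unlabeled = fu$rt[ci$i], mz_unlabeled = fu$mz[ci$i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$rt_unlabeled, out$mz_unlabeled), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive full enumeration of ion formulas over bounds via expand.grid
oracle_enumerate <- function(observed_mz, polarity, bounds, ppm_tol,
                             rdbe_min = -0.5) {
  em <- isoshift::element_masses()
  val <- c(C = 4, H = 1, D = 1, N = 3, O = 2, S = 2, F = 1, P = 3,
           Cl = 1, Br = 1, I = 1)
  grids <- lapply(bounds, function(b) seq.int(b[1], b[2]))
  g <- do.call(expand.grid, grids)
  m <- as.matrix(g) %*% em[names(bounds)]
  ec <- isoshift::electron_mass()
  theo <- m - switch(polarity, positive = ec, negative = -ec, neutral = 0)
  ppm <- (theo - observed_mz) / observed_mz * 1e6
  rd <- 1 + as.matrix(g) %*% (val[names(bounds)] - 2) / 2
  keep <- abs(ppm) <= ppm_tol & rd >= rdbe_min & rowSums(g) > 0
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  forms <- vapply(seq_len(nrow(g)), function(i) {
    v <- unlist(g[i, ]); isoshift::format_formula(v[v > 0])
  }, character(1))
  sort(forms)
}

# brute-force single-linkage clustering of retention times: iteratively
# merge the two clusters with the smallest inter-cluster gap <= window
oracle_single_linkage <- function(rts, window) {
  clusters <- as.list(seq_along(rts))
  repeat {
    best <- NULL; bestd <- Inf
    if (length(clusters) < 2L) break
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- min(abs(outer(rts[clusters[[a]]], rts[clusters[[b]]], "-")))
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    if (is.null(best) || bestd > window) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  length(clusters)
}

# random small feature-map pair for property tests
random_run_pair <- function(seed, n_max = 50L) {
  set.seed(seed)
  n_u <- sample.int(n_max, 1L)
  n_l <- sample.int(n_max, 1L)
  mk <- function(n, tag) {
    # cluster m/z and rt so that the shift window is frequently populated
    data.frame(id = sprintf("%s%03d", tag, seq_len(n)),
               rt = round(runif(n, 0, 3), 2),
               mz = round(runif(n, 100, 140), 2),
               intensity = exp(runif(n, log(10), log(1000))))
  }
  list(unlabeled = isoshift::feature_map(mk(n_u, "u"), "ru", "positive",
                                         "unlabeled"),
       labeled = isoshift::feature_map(mk(n_l, "l"), "rl", "positive",
                                       "labeled"))
}

# every emitted pair must satisfy all three criteria (inclusive bounds)
expect_pairs_sound <- function(pairs, params) {
  if (nrow(pairs) == 0L) return(invisible())
  testthat::expect_true(all(abs(pairs$delta_mz - params$mass_shift) <=
                              params$mass_tol))
  testthat::expect_true(all(abs(pairs$delta_rt) <= params$rt_tol))
  if (params$require_intensity)
    testthat::expect_true(all(abs(pairs$delta_intensity_pct) <=
                                100 * params$intensity_drift + 1e-9))
}
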