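gaussian_scans <- function(apex_rt, apex_int, mz, times,
                           sigma = 0.05) {
  lapply(times, function(t) {
    h <- apex_int * exp(-(t - apex_rt)^2 / (2 * sigma^2))
    centroid_scan(t, mz, h)
  })
}

test_that("a single Gaussian elution trace yields one apex feature", {
  times <- seq(0.90, 1.10, by = 0.02)  # 11 scans, apex at scan 6 (t = 1.00)
  scans <- gaussian_scans(1.00, 1000, 315.17, times)
  fm <- detect_features(scans, detection_params(mz_tol = 0.02,
                                                min_scans = 3))
  expect_equal(nrow(fm$features), 1L)
  expect_equal(fm$features$rt, 1.00)
  expect_equal(fm$features$intensity, 1000)
  expect_equal(fm$features$mz, 315.17, tolerance = 1e-9)
})

test_that("co-eluting traces 0.5 amu apart resolve into two features", {
  times <- seq(0.90, 1.10, by = 0.02)
  scans <- lapply(times, function(t) {
    h <- 1000 * exp(-(t - 1.0)^2 / (2 * 0.05^2))
    centroid_scan(t, c(315.17, 315.67), c(h, 0.8 * h))
  })
  fm <- detect_features(scans, detection_params(mz_tol = 0.02))
  expect_equal(nrow(fm$features), 2L)
  expect_equal(sort(fm$features$mz), c(315.17, 315.67), tolerance = 1e-9)
})

test_that("detection handles empty input and rejects unsorted scans", {
  expect_equal(nrow(detect_features(list())$features), 0L)
  sc <- list(centroid_scan(1.0, 100, 10), centroid_scan(0.5, 100, 10))
  expect_error(detect_features(sc), "sorted")
})

test_that("feature count is non-increasing in min_scans and min_intensity", {
  spec <- synthetic_spec(n_matrix_ions = 10L, n_noise_ions = 0L, seed = 11L)
  scans <- generate_scans(spec, gradient_length = 14, scan_interval = 0.02)
  counts_scans <- vapply(c(1L, 3L, 6L, 12L), function(ms) {
    nrow(detect_features(scans$unlabeled,
                         detection_params(min_scans = ms))$features)
  }, integer(1))
  expect_true(all(diff(counts_scans) <= 0))
  counts_int <- vapply(c(0, 1e3, 1e4, 1e5), function(mi) {
    nrow(detect_features(scans$unlabeled,
                         detection_params(min_intensity = mi))$features)
  }, integer(1))
  expect_true(all(diff(counts_int) <= 0))
})

test_that("detection recovers planted ground truth from noiseless scans", {
  spec <- synthetic_spec(n_matrix_ions = 0L, n_noise_ions = 0L,
                         mz_sigma = 0, seed = 5L)
  scans <- generate_scans(spec, gradient_length = 14, scan_interval = 0.02)
  fm <- detect_features(scans$unlabeled, detection_params())
  truth <- generate_paired_runs(spec)$unlabeled$features
  expect_equal(nrow(fm$features), nrow(truth))
  o <- order(fm$features$mz); ot <- order(truth$mz)
  expect_equal(fm$features$mz[o], truth$mz[ot], tolerance = 1e-6)
  expect_true(all(abs(fm$features$rt[o] - truth$rt[ot]) <= 0.02 + 1e-9))
})

test_that("single metabolite round-trips scans -> detection per run", {
  spec <- synthetic_spec(metabolites = data.frame(mz = 373.1211, rt = 8.64,
                                                  intensity = 1e5),
                         n_matrix_ions = 0L, n_noise_ions = 0L, seed = 3L)
  scans <- generate_scans(spec, gradient_length = 12, scan_interval = 0.02)
  for (run in c("unlabeled", "labeled")) {
    fm <- detect_features(scans[[run]], detection_params())
    expect_equal(nrow(fm$features), 1L, info = run)
  }
  # degenerate sampling: interval beyond gradient length -> at most one scan
  wide <- generate_scans(spec, gradient_length = 12, scan_interval = 15)
  expect_lte(length(wide$unlabeled), 1L)
})

test_that("alignment matches identical maps one-to-one with zero offset", {
  m <- feature_map(data.frame(rt = c(1, 2, 3), mz = c(100, 200, 300),
                              intensity = c(5, 10, 20),
                              id = c("a", "b", "c")))
  al <- align_runs(m, m, rt_tol = 0.1, mz_tol = 0.01)
  expect_equal(al$id_a, al$id_b)
  expect_equal(al$rt_offset, c(0, 0, 0))
})

test_that("disjoint m/z ranges align to absent partners", {
  a <- feature_map(data.frame(rt = 1:2, mz = c(100, 110),
                              intensity = c(1, 2)))
  b <- feature_map(data.frame(rt = 1:2, mz = c(500, 510),
                              intensity = c(1, 2)))
  al <- align_runs(a, b, rt_tol = 0.5, mz_tol = 0.01)
  expect_equal(nrow(al), 4L)
  expect_true(all(is.na(al$id_b[!is.na(al$id_a)])))
  expect_true(all(is.na(al$id_a[is.na(al$id_b)][3:4])))
})

test_that("greedy alignment equals minimum-cost assignment on a toy case", {
  # one ambiguous candidate: a2 could match b2 or b3; exhaustive assignment
  # over all one-to-one matchings is the oracle
  a <- feature_map(data.frame(rt = c(1.00, 2.00, 3.00),
                              mz = c(100.000, 200.000, 300.000),
                              intensity = c(1, 1, 1),
                              id = c("a1", "a2", "a3")))
  b <- feature_map(data.frame(rt = c(1.01, 2.02, 2.05),
                              mz = c(100.001, 200.002, 200.004),
                              intensity = c(1, 1, 1),
                              id = c("b1", "b2", "b3")))
  rt_tol <- 0.1; mz_tol <- 0.01
  al <- align_runs(a, b, rt_tol, mz_tol)
  cost <- function(i, j) {
    abs(a$features$rt[i] - b$features$rt[j]) / rt_tol +
      abs(a$features$mz[i] - b$features$mz[j]) / mz_tol
  }
  feasible <- function(i, j) {
    abs(a$features$rt[i] - b$features$rt[j]) <= rt_tol &&
      abs(a$features$mz[i] - b$features$mz[j]) <= mz_tol
  }
  best <- NULL; best_cost <- Inf
  for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))) {
    ok <- vapply(1:3, function(i) feasible(i, perm[i]), logical(1))
    if (!any(ok)) next
    total <- sum(vapply(which(ok), function(i) cost(i, perm[i]),
                        numeric(1)))
    n_matched <- sum(ok)
    # maximize matches, then minimize cost
    if (is.null(best) || n_matched > best$n ||
        (n_matched == best$n && total < best_cost)) {
      best <- list(perm = perm, ok = ok, n = n_matched)
      best_cost <- total
    }
  }
  got <- al[!is.na(al$id_a) & !is.na(al$id_b), ]
  expect_equal(nrow(got), best$n)
  for (i in which(best$ok)) {
    expect_equal(got$id_b[got$id_a == a$features$id[i]],
                 b$features$id[best$perm[i]])
  }
})

test_that("alignment never pairs features beyond either tolerance", {
  for (seed in 1:20) {
    rp <- random_run_pair(seed, n_max = 30L)
    al <- align_runs(rp$unlabeled, rp$labeled, rt_tol = 0.1, mz_tol = 0.05)
    both <- al[!is.na(al$id_a) & !is.na(al$id_b), ]
    if (nrow(both)) {
      expect_true(all(abs(both$rt_a - both$rt_b) <= 0.1))
      expect_true(all(abs(both$mz_a - both$mz_b) <= 0.05))
      expect_false(anyDuplicated(both$id_a) > 0)
      expect_false(anyDuplicated(both$id_b) > 0)
    }
  }
})
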