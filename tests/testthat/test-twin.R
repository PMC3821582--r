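test_that("the published pioglitazone runs yield exactly the 8 pairs", {
  runs <- example_runs("pioglitazone")
  pairs <- find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
  expect_equal(nrow(pairs), 8L)
  expect_false(any(grepl("dec", pairs$id_unlabeled)))
  expect_false(any(grepl("dec", pairs$id_labeled)))
  expect_pairs_sound(pairs, runs$params)
  # deltas follow the reporting conventions exactly
  rep <- report_pairs(pairs)
  lab <- rep[seq(2, 16, by = 2), ]
  expect_equal(lab$delta_mz,
               c("+4.02", "+4.03", "+4.02", "+4.02", "+4.02", "+4.02",
                 "+4.02", "+4.02"))
  expect_equal(lab$delta_rt,
               c("-0.04", "-0.02", "-0.03", "-0.03", "-0.03", "-0.04",
                 "-0.04", "-0.09"))
  expect_equal(lab$delta_intensity_pct,
               c("2", "-39", "-10", "-6", "-33", "-41", "-8", "-5"))
})

test_that("the published flurbiprofen runs yield exactly the 7 pairs", {
  runs <- example_runs("flurbiprofen")
  pairs <- find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
  expect_equal(nrow(pairs), 7L)
  expect_false(any(grepl("dec", c(pairs$id_unlabeled, pairs$id_labeled))))
  expect_pairs_sound(pairs, runs$params)
  rep <- report_pairs(pairs)
  lab <- rep[seq(2, 14, by = 2), ]
  expect_equal(lab$delta_mz,
               c("+3.02", "+3.01", "+3.02", "+3.01", "+3.02", "+3.02",
                 "+3.01"))
  expect_equal(lab$delta_intensity_pct,
               c("-4", "-7", "-8", "7", "13", "-2", "5"))
})

test_that("empty inputs and guard rails behave", {
  runs <- example_runs("pioglitazone")
  empty_u <- feature_map(NULL, label_status = "unlabeled")
  empty_l <- feature_map(NULL, label_status = "labeled")
  expect_equal(nrow(find_twin_pairs(empty_u, runs$labeled, runs$params)), 0L)
  expect_equal(nrow(find_twin_pairs(runs$unlabeled, empty_l, runs$params)),
               0L)
  expect_error(find_twin_pairs(runs$labeled, runs$unlabeled, runs$params),
               "label_status")
  neg <- runs$labeled; neg$polarity <- "negative"
  expect_error(find_twin_pairs(runs$unlabeled, neg, runs$params),
               "polarity")
  expect_error(filter_params(-1, 0.04), "mass_shift")
  expect_error(filter_params(4, 0), "mass_tol")
})

test_that("mixture mode recovers the same pairs from one merged run", {
  runs <- example_runs("pioglitazone")
  merged <- feature_map(rbind(runs$unlabeled$features,
                              runs$labeled$features),
                        run_id = "mix", polarity = "positive",
                        label_status = "mixture")
  mix <- find_twin_pairs_mixture(merged, runs$params)
  two <- find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
  expect_equal(nrow(mix), 8L)
  expect_equal(mix$id_unlabeled, two$id_unlabeled)
  expect_equal(mix$id_labeled, two$id_labeled)
  # lighter member always reported as unlabeled
  expect_true(all(mix$delta_mz > 0))
  # single feature cannot pair with itself
  single <- feature_map(data.frame(rt = 1, mz = 100, intensity = 5),
                        label_status = "mixture")
  expect_equal(nrow(find_twin_pairs_mixture(single, runs$params)), 0L)
  # correct shift but excessive rt gap is rejected
  two_feat <- feature_map(data.frame(rt = c(1.0, 1.3), mz = c(100, 104),
                                     intensity = c(5, 5)),
                          label_status = "mixture")
  expect_equal(nrow(find_twin_pairs_mixture(two_feat, runs$params)), 0L)
  expect_error(find_twin_pairs_mixture(runs$unlabeled, runs$params),
               "mixture")
})

test_that("twin filter equals the brute-force oracle on random maps", {
  params <- filter_params(4.00, 0.04, 0.1, 0.5)
  for (seed in 201:260) {
    rp <- random_run_pair(seed)
    got <- find_twin_pairs(rp$unlabeled, rp$labeled, params)
    want <- oracle_twin_pairs(rp$unlabeled, rp$labeled, params)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$id_unlabeled, want$id_unlabeled,
                   info = paste("seed", seed))
      expect_equal(got$id_labeled, want$id_labeled,
                   info = paste("seed", seed))
    }
    expect_pairs_sound(got, params)
    if (nrow(got)) expect_true(all(got$delta_mz > 0))
  }
})

test_that("pair count never decreases as tolerances widen", {
  runs <- example_runs("pioglitazone")
  n_by_mass <- vapply(c(0.01, 0.04, 0.1, 0.5), function(mt) {
    nrow(find_twin_pairs(runs$unlabeled, runs$labeled,
                         filter_params(4.00, mt, 0.1, 0.5)))
  }, integer(1))
  expect_true(all(diff(n_by_mass) >= 0))
  n_by_rt <- vapply(c(0.01, 0.05, 0.1, 0.3), function(rt) {
    nrow(find_twin_pairs(runs$unlabeled, runs$labeled,
                         filter_params(4.00, 0.04, rt, 0.5)))
  }, integer(1))
  expect_true(all(diff(n_by_rt) >= 0))
  n_by_drift <- vapply(c(0.05, 0.2, 0.5, 1.0), function(dr) {
    nrow(find_twin_pairs(runs$unlabeled, runs$labeled,
                         filter_params(4.00, 0.04, 0.1, dr)))
  }, integer(1))
  expect_true(all(diff(n_by_drift) >= 0))
})

test_that("co-elution grouping reproduces the published group structure", {
  runs <- example_runs("flurbiprofen")
  pairs <- find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
  groups <- group_coeluting(pairs, rt_window = 0.05)
  expect_equal(length(groups), 4L)
  sizes <- vapply(groups, function(g) nrow(g$pairs), integer(1))
  expect_equal(sort(sizes), c(1L, 1L, 1L, 4L))
  big <- groups[[which.max(sizes)]]
  expect_equal(big$precursor_mz, 259.07)
  expect_equal(round(big$rt_center, 1), 11.5)

  prs <- example_runs("pioglitazone")
  pp <- find_twin_pairs(prs$unlabeled, prs$labeled, prs$params)
  expect_equal(length(group_coeluting(pp, rt_window = 0.02)), 8L)
  # at 0.05 the 8.09/8.12 ions merge by rt alone; the neutral-loss check
  # splits them back apart (m/z difference ~101 matches no loss)
  expect_equal(length(group_coeluting(pp, rt_window = 0.05)), 7L)
  expect_equal(length(group_coeluting(pp, rt_window = 0.05,
                                      losses = default_neutral_losses())),
               8L)
  expect_equal(length(group_coeluting(pairs[0, ], 0.05)), 0L)
  expect_error(group_coeluting(pairs, -1), "rt_window")
})

test_that("grouping matches a brute-force single-linkage oracle", {
  runs <- example_runs("flurbiprofen")
  pairs <- find_twin_pairs(runs$unlabeled, runs$labeled, runs$params)
  for (w in c(0.01, 0.02, 0.05, 0.3, 1.0)) {
    expect_equal(length(group_coeluting(pairs, rt_window = w)),
                 oracle_single_linkage(pairs$rt_unlabeled, w),
                 info = paste("window", w))
  }
  set.seed(99)
  rts <- round(runif(30, 0, 5), 2)
  fake <- structure(
    data.frame(id_unlabeled = sprintf("p%02d", 1:30),
               id_labeled = sprintf("q%02d", 1:30),
               rt_unlabeled = rts, rt_labeled = rts - 0.03,
               mz_unlabeled = runif(30, 100, 500),
               mz_labeled = runif(30, 100, 500) + 4,
               rel_intensity_unlabeled = 50, rel_intensity_labeled = 50,
               delta_rt = -0.03, delta_mz = 4, delta_intensity_pct = 0),
    class = c("twin_pairs", "data.frame"))
  for (w in c(0.05, 0.1, 0.5)) {
    expect_equal(length(group_coeluting(fake, rt_window = w)),
                 oracle_single_linkage(rts, w))
  }
})

test_that("in-source fragments are annotated by nearest neutral loss", {
  # accurate-mass co-eluting flurbiprofen ions
  df <- data.frame(
    id_unlabeled = c("p259", "p247", "p229", "p214"),
    id_labeled = c("q259", "q247", "q229", "q214"),
    rt_unlabeled = c(11.50, 11.50, 11.50, 11.50),
    rt_labeled = c(11.45, 11.46, 11.45, 11.46),
    mz_unlabeled = c(259.07753, 247.07723, 229.06721, 214.07995),
    mz_labeled = c(262.09, 250.09, 232.08, 217.09),
    rel_intensity_unlabeled = 10, rel_intensity_labeled = 10,
    delta_rt = -0.05, delta_mz = 3.02, delta_intensity_pct = 0)
  pairs <- structure(df, class = c("twin_pairs", "data.frame"))
  group <- group_coeluting(pairs, rt_window = 0.05)[[1]]
  ann <- annotate_neutral_losses(group, tol = 0.005)$fragment_annotations
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$label[ann$id == "p229"], "CH2O")
  expect_equal(round(ann$loss_mass[ann$id == "p229"], 5), 30.01032)
  expect_equal(ann$label[ann$id == "p214"], "CO2H")
  expect_equal(ann$label[ann$id == "p247"], "C")
  # unmatched loss stays unassigned
  odd <- structure(
    data.frame(id_unlabeled = c("a", "b"), id_labeled = c("c", "d"),
               rt_unlabeled = c(5, 5), rt_labeled = c(4.97, 4.97),
               mz_unlabeled = c(400, 377.77), mz_labeled = c(404, 381.77),
               rel_intensity_unlabeled = 10, rel_intensity_labeled = 10,
               delta_rt = -0.03, delta_mz = 4, delta_intensity_pct = 0),
    class = c("twin_pairs", "data.frame"))
  g2 <- group_coeluting(odd, rt_window = 0.05)[[1]]
  ann2 <- annotate_neutral_losses(g2, tol = 0.005)$fragment_annotations
  expect_equal(ann2$label, "unassigned")
  # single-member group gets an empty annotation table
  g3 <- group_coeluting(odd[1, ], rt_window = 0.05)[[1]]
  expect_equal(nrow(annotate_neutral_losses(g3)$fragment_annotations), 0L)
})

test_that("report formatting handles the degenerate identical pair", {
  df <- data.frame(
    id_unlabeled = "u", id_labeled = "l",
    rt_unlabeled = 5.00, rt_labeled = 5.00,
    mz_unlabeled = 300.00, mz_labeled = 304.00,
    rel_intensity_unlabeled = 42.00, rel_intensity_labeled = 42.00,
    delta_rt = 0, delta_mz = 4.00, delta_intensity_pct = 0)
  rep <- report_pairs(structure(df, class = c("twin_pairs", "data.frame")))
  expect_equal(rep$delta_rt[2], "0.00")
  expect_equal(rep$delta_intensity_pct[2], "0")
  expect_equal(rep$delta_mz[2], "+4.00")
})
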