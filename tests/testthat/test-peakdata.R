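make_map <- function(n = 3, ...) {
  feature_map(data.frame(rt = seq_len(n), mz = 100 + seq_len(n),
                         intensity = 10 * seq_len(n)), ...)
}

test_that("feature tables read, write and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  fm <- feature_map(data.frame(rt = c(8.64, 12.0), mz = c(373.121, 357.127),
                               intensity = c(100, 5.05),
                               id = c("a", "b")),
                    run_id = "r1", polarity = "positive",
                    label_status = "unlabeled")
  write_feature_table(fm, path)
  back <- read_feature_table(path, run_id = "r1", polarity = "positive",
                             label_status = "unlabeled")
  expect_identical(back$features[c("id", "rt", "mz", "intensity")],
                   fm$features[c("id", "rt", "mz", "intensity")])
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reader is header-driven and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity\trt_min", "315.17\t1.71\t6.78"), path)
  fm <- read_feature_table(path)
  expect_equal(fm$features$rt, 6.78)
  expect_equal(fm$features$mz, 315.17)

  writeLines("rt_min\tmz\tintensity", path)
  expect_equal(nrow(read_feature_table(path)$features), 0L)

  writeLines(c("rt_min\tmz", "1\t2"), path)
  expect_error(read_feature_table(path), "intensity")

  writeLines(c("rt_min\tmz\tintensity", "1.0\t100.2\tfifty"), path)
  expect_error(read_feature_table(path), "row 1")

  writeLines(c("rt_sec\tmz\tintensity", "60\t100.2\t5"), path)
  expect_error(read_feature_table(path), "minutes")

  expect_error(read_feature_table(file.path(tempdir(), "nope.tsv")),
               "no such file")
})

test_that("relative intensity is base-peak-normalized percent", {
  fm <- feature_map(data.frame(rt = 1:3, mz = c(355.11, 373.12, 332.13),
                               intensity = c(1.35, 100.0, 5.05),
                               id = c("a", "b", "c")))
  expect_equal(relative_intensity(fm, "b"), 100)
  expect_equal(relative_intensity(fm, "a"), 1.35)
  expect_equal(relative_intensity(fm, "c"), 5.05)
  half <- feature_map(data.frame(rt = 1:2, mz = c(100, 200),
                                 intensity = c(50, 100)))
  expect_equal(relative_intensity(half, 1), 50)
  expect_error(relative_intensity(fm, "zz"), "not found")
})

test_that("reference-ion subtraction removes within-tolerance features", {
  sample <- feature_map(data.frame(rt = c(8.64, 12.0),
                                   mz = c(373.121, 357.127),
                                   intensity = c(10, 20)))
  ref <- feature_map(data.frame(rt = 12.0, mz = 357.127, intensity = 99))
  out <- subtract_reference_ions(sample, ref, mz_tol = 0.01, rt_tol = 0.1)
  expect_equal(out$features$mz, 373.121)
  # identity on empty reference
  empty <- feature_map(NULL)
  expect_identical(subtract_reference_ions(sample, empty)$features,
                   sample$features)
  # reference = sample empties the map
  expect_equal(nrow(subtract_reference_ions(sample, sample)$features), 0L)
  # idempotence and conservation
  once <- subtract_reference_ions(sample, ref)
  twice <- subtract_reference_ions(once, ref)
  expect_identical(once$features, twice$features)
  removed <- nrow(sample$features) - nrow(once$features)
  expect_equal(nrow(once$features) + removed, nrow(sample$features))
  # polarity guard
  neg <- feature_map(data.frame(rt = 1, mz = 2, intensity = 3),
                     polarity = "negative")
  expect_error(subtract_reference_ions(sample, neg), "polarity")
})

test_that("centroid scans round-trip through JSON lines", {
  scans <- list(centroid_scan(0.10, c(200.1, 100.5), c(5, 10)),
                centroid_scan(0.12, numeric(0), numeric(0)),
                centroid_scan(0.14, 150.2, 7))
  expect_equal(scans[[1]]$mz, c(100.5, 200.1))  # stored sorted
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_scans_jsonl(scans, path)
  back <- read_scans_jsonl(path)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$mz, scans[[1]]$mz)
  expect_equal(back[[1]]$intensity, scans[[1]]$intensity)
  expect_equal(vapply(back, `[[`, numeric(1), "scan_time"),
               c(0.10, 0.12, 0.14))
  expect_error(centroid_scan(-1, 1, 1), "scan_time")
})
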