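make_subject_csv <- function(path, m) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
}

test_that("ROI reader harmonises region order and enforces labels", {
  d <- withr::local_tempdir()
  m1 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  m2 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("r2", "r1", "r3")))
  make_subject_csv(file.path(d, "s1.csv"), m1)
  make_subject_csv(file.path(d, "s2.csv"), m2)
  co <- read_roi_timeseries(c(s1 = file.path(d, "s1.csv"),
                              s2 = file.path(d, "s2.csv")),
                            c(s1 = "A", s2 = "B"))
  expect_s3_class(co, "CohortSeries")
  expect_equal(length(co$subject_ids), 2L)
  expect_equal(co$region_ids, c("r1", "r2", "r3"))
  # columns of s2 were permuted back to canonical order
  expect_equal(unname(co$data$s2[, "r2"]), unname(m2[, "r2"]))
  expect_equal(unname(co$data$s2[, "r1"]), unname(m2[, "r1"]))
  expect_error(read_roi_timeseries(c(s1 = file.path(d, "s1.csv")),
                                   c(other = "A")),
               "no group label")
  # mismatched region set rejected
  m3 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("r1", "r9")))
  make_subject_csv(file.path(d, "s3.csv"), m3)
  expect_error(read_roi_timeseries(c(s1 = file.path(d, "s1.csv"),
                                     s3 = file.path(d, "s3.csv")),
                                   c(s1 = "A", s3 = "B")),
               "mismatched region set")
})

test_that("non-numeric cells are reported with coordinates", {
  d <- withr::local_tempdir()
  writeLines(c("r1,r2", "1.0,2.0", "NA,3.0"), file.path(d, "bad.csv"))
  expect_error(read_roi_timeseries(c(s1 = file.path(d, "bad.csv")),
                                   c(s1 = "A")),
               "row 2, column 'r1'")
})

test_that("cohort round-trips through manifest + CSVs bit-identically", {
  tm <- make_truth(K = 2, R = 3, separation = 3, seed = 7)
  sim <- simulate_cohort(tm, c(2, 2), T = 40, seed = 8)
  d <- withr::local_tempdir()
  man <- write_cohort(sim$cohort, d)
  back <- read_cohort_manifest(man)
  expect_equal(back$subject_ids, sim$cohort$subject_ids)
  expect_equal(back$group_labels, sim$cohort$group_labels)
  expect_equal(back$tr_seconds, sim$cohort$tr_seconds)
  for (sid in back$subject_ids)
    expect_identical(unname(back$data[[sid]]), unname(sim$cohort$data[[sid]]))
})

test_that("preprocessing trims, standardises, and flags degenerate traces", {
  set.seed(1)
  raw <- cohort_series(
    list(s1 = matrix(rnorm(1445 * 2, mean = 5, sd = 3), 1445, 2),
         s2 = matrix(rnorm(1445 * 2, mean = -2, sd = 0.5), 1445, 2)),
    tr_seconds = 0.81, group_labels = c(s1 = "A", s2 = "B"))
  prep <- preprocess_series(raw)
  expect_equal(n_volumes(prep), 1400L)
  for (m in prep$data) {
    expect_equal(unname(colMeans(m)), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(m, 2, sd)), c(1, 1), tolerance = 1e-12)
  }
  # idempotent with no trimming
  again <- preprocess_series(prep, trim_start = 0, trim_end = 0)
  expect_equal(again$data$s1, prep$data$s1, tolerance = 1e-12)
  # constant trace errors with subject/region named
  bad <- raw
  bad$data$s2[, 2] <- 5
  expect_error(preprocess_series(bad), "s2.*r2")
  # pooled scaling standardises the concatenated matrix, not each subject
  pooled <- preprocess_series(raw, scale = "pooled")
  allm <- do.call(rbind, pooled$data)
  expect_equal(unname(colMeans(allm)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(allm, 2, sd)), c(1, 1), tolerance = 1e-3)
})

test_that("scene masks follow the half-open post-trim convention", {
  sc <- scene_table(data.frame(onset_s = 8.1, duration_s = 1.62,
                               valence = "pos"))
  mask <- scenes_to_mask(sc, tr_seconds = 0.81, n_volumes = 20,
                         trim_start = 10)
  expect_equal(which(mask), c(1L, 2L))  # 0-based volumes {0, 1}
  # empty table -> all FALSE
  empty <- scene_table(data.frame(onset_s = numeric(),
                                  duration_s = numeric(),
                                  valence = character()))
  expect_false(any(scenes_to_mask(empty, 0.81, 20, 10)))
  # adjacent scenes: boundary volume belongs to the later scene, no double
  # count; total TRUE equals the sum of per-scene counts
  two <- scene_table(data.frame(onset_s = c(8.1, 9.72),
                                duration_s = c(1.62, 1.62),
                                valence = c("pos", "neg")))
  m2 <- scenes_to_mask(two, 0.81, 20, 10)
  per_scene <- vapply(seq_len(2), function(i)
    sum(scenes_to_mask(two[i, ], 0.81, 20, 10)), 0L)
  expect_equal(sum(m2), sum(per_scene))
  expect_equal(which(m2), 1:4)
  # scene beyond movie end is rejected
  far <- scene_table(data.frame(onset_s = 1000, duration_s = 5,
                                valence = "pos"))
  expect_error(scenes_to_mask(far, 0.81, 20, 10), "beyond the movie end")
  # overlapping scenes rejected at validation
  expect_error(scene_table(data.frame(onset_s = c(0, 1), duration_s = c(2, 2),
                                      valence = c("a", "b"))),
               "overlap")
})

test_that("OpenFace reader returns 16 analysis AUs, excludes AU45, keeps missingness", {
  d <- withr::local_tempdir()
  n <- 50
  aus <- c(statesync:::AU_ANALYSIS_SET, "AU45")
  df <- data.frame(frame = seq_len(n), timestamp = (seq_len(n) - 1) / 10,
                   confidence = 0.98, success = rep(c(1L, 0L), c(n - 2L, 2L)))
  for (a in aus) df[[paste0(a, "_r")]] <- runif(n, 0, 3)
  f <- file.path(d, "face.csv")
  utils::write.csv(df, f, row.names = FALSE)
  of <- read_openface_csv(f)
  expect_equal(ncol(of$intensities), 16L)
  expect_false("AU45" %in% colnames(of$intensities))
  expect_equal(of$excluded, "AU45")
  expect_equal(of$fps, 10)
  # failed frames are NA, not zero
  expect_true(all(is.na(of$intensities[(n - 1):n, ])))
  expect_equal(of$n_missing, 2L)
  # missing AU column reported by name
  df2 <- df[, setdiff(names(df), "AU12_r")]
  f2 <- file.path(d, "face2.csv")
  utils::write.csv(df2, f2, row.names = FALSE)
  expect_error(read_openface_csv(f2), "AU12")
})
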