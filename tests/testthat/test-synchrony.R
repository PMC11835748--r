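test_that("windowed consistency counts window visits as percentages", {
  # subject 1 occupies state 1 only at volume 10; subject 2 never does
  T <- 20
  p1 <- rep(2L, T); p1[10] <- 1L
  p2 <- rep(2L, T)
  ps <- state_path_set(list(a = p1, b = p2), K = 2)
  cc <- windowed_consistency(ps, w = 3)
  expect_equal(cc$value[1, 7:13], rep(50, 7))
  expect_equal(cc$value[1, c(1:6, 14:20)], rep(0, 13))
  # state 2 is present in all subjects everywhere
  expect_equal(cc$value[2, ], rep(100, T))
  # w = 0 degenerates to the instantaneous state share
  cc0 <- windowed_consistency(ps, w = 0)
  expect_equal(cc0$value[1, ], c(rep(0, 9), 50, rep(0, 10)))
  # identical paths give 100% for the occupied state at every volume
  same <- state_path_set(list(a = p1, b = p1, c = p1), K = 2)
  ccs <- windowed_consistency(same, w = 3)
  occupied <- ifelse(seq_len(T) %in% 7:13, 1, 2)
  for (v in seq_len(T)) expect_equal(ccs$value[occupied[v], v], 100)
  # monotone non-decreasing in w; bounded in [0, 100]
  for (w in 0:3) {
    a <- windowed_consistency(ps, w = w)$value
    b <- windowed_consistency(ps, w = w + 1)$value
    expect_true(all(b >= a - 1e-12))
    expect_true(all(a >= 0 & a <= 100))
  }
  expect_error(windowed_consistency(ps, members = character(0)), "empty")
})

test_that("between-group null surfaces behave like resampling quantiles", {
  tm <- make_truth(K = 3, R = 3, separation = 4, seed = 61)
  sim <- simulate_cohort(tm, c(4, 5), T = 150, seed = 62)
  # n_iter = 1: the surface is that single pseudo-group's curve
  b1 <- between_group_null(sim$paths, c(4, 5), n_iter = 1, seed = 63)
  set.seed(63)
  idx <- sample.int(9)
  cA <- windowed_consistency(sim$paths, idx[1:4])
  cB <- windowed_consistency(sim$paths, idx[5:9])
  expect_equal(b1$threshold_A, cA$value, tolerance = 1e-12)
  expect_equal(b1$threshold_B, cB$value, tolerance = 1e-12)
  expect_error(between_group_null(sim$paths, c(4, 4)), "sum to the cohort")
  # planted 100%-adherence window: observed group-A curve exceeds its
  # null surface throughout the window
  pl <- planted_sync("A", state = 1, windows = list(c(60, 90)),
                     adherence = 1)
  simp <- simulate_cohort(tm, c(10, 10), T = 150, planted = list(pl),
                          seed = 64)
  obs <- windowed_consistency(simp$paths, which(
    simp$cohort$group_labels == "A"))
  btw <- between_group_null(simp$paths, c(10, 10), n_iter = 400, seed = 65)
  expect_true(all(obs$value[1, 63:87] > btw$threshold_A[1, 63:87]))
})

test_that("within-group null matches the closed-form window-coverage law", {
  # i.i.d. uniform 2-state chain: P(state visits a 7-volume window)
  # = 1 - (1/2)^7, so every null consistency mean concentrates there
  trans <- matrix(0.5, 2, 2)
  set.seed(66)
  big <- state_path_set(lapply(1:40, function(i)
    sample.int(2, 400, replace = TRUE)), K = 2)
  wg <- within_group_null(big, n_iter = 120, seed = 67, transmat = trans)
  expected <- (1 - 0.5^7) * 100
  # thresholds are 95th percentiles of means across subjects and volumes,
  # so they sit within a fraction of a percent of the coverage law
  expect_equal(unname(wg$threshold), rep(expected, 2), tolerance = 0.01)
  # seeded determinism
  wg2 <- within_group_null(big, n_iter = 120, seed = 67, transmat = trans)
  expect_identical(wg$threshold, wg2$threshold)
  # surrogates destroy cross-subject alignment: planting in the observed
  # paths leaves the null untouched (same transmat supplied)
  tm <- make_truth(K = 2, R = 2, separation = 3, seed = 68)
  pl <- planted_sync("A", state = 1, windows = list(c(100, 160)),
                     adherence = 1)
  simp <- simulate_cohort(tm, c(20, 20), T = 400, planted = list(pl),
                          seed = 69)
  sub <- state_path_set(simp$paths$paths, K = 2)  # same size/length as big
  wg3 <- within_group_null(sub, n_iter = 120, seed = 67, transmat = trans)
  expect_identical(wg3$threshold, wg$threshold)
  expect_error(within_group_null(state_path_set(list(a = c(1L, 2L)), K = 2)),
               "at least 2")
})

test_that("event flagging applies the conjunction rule over the mask", {
  val <- matrix(20, 2, 30)
  val[1, 11:20] <- 90
  curve <- structure(list(value = val, w = 3L, n_members = 10,
                          members = 1:10), class = "ConsistencyCurve")
  between <- matrix(50, 2, 30)
  within <- c(60, 60)
  mask <- rep(TRUE, 30)
  ev <- flag_sync_events(curve, between, within, mask)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 11L)
  expect_equal(ev$end, 20L)
  expect_equal(ev$peak, 90)
  # below either threshold -> nothing (conjunction)
  ev2 <- flag_sync_events(curve, matrix(95, 2, 30), within, mask)
  expect_equal(nrow(ev2), 0L)
  ev3 <- flag_sync_events(curve, between, c(95, 95), mask)
  expect_equal(nrow(ev3), 0L)
  # masked-out volumes are never flagged
  mask2 <- rep(FALSE, 30); mask2[11:14] <- TRUE
  ev4 <- flag_sync_events(curve, between, within, mask2)
  expect_equal(ev4$end, 14L)
  # min_run filters short events
  ev5 <- flag_sync_events(curve, between, within, mask2, min_run = 5)
  expect_equal(nrow(ev5), 0L)
})

test_that("full-cohort consistency ignores group labels and degenerate inputs flow through", {
  tm <- make_truth(K = 2, R = 2, separation = 3, seed = 71)
  sim <- simulate_cohort(tm, c(3, 3), T = 100, seed = 72)
  all1 <- windowed_consistency(sim$paths)
  all2 <- windowed_consistency(sim$paths, members = sample(1:6))
  expect_equal(all1$value, all2$value, tolerance = 1e-12)
  # identical paths everywhere: analysis runs and returns well-formed events
  ident <- state_path_set(rep(list(rep(1L, 60)), 6), K = 2)
  names(ident$paths) <- paste0("s", 1:6)
  syn <- synchrony_analysis(ident, rep(c("A", "B"), each = 3),
                            mask = rep(TRUE, 60), n_iter = 50, seed = 73)
  for (g in c("A", "B")) {
    ev <- syn$events[[g]]
    expect_true(is.data.frame(ev))
    if (nrow(ev)) {
      expect_true(all(ev$start <= ev$end))
      expect_true(all(ev$peak <= 100))
    }
  }
})
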