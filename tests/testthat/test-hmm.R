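test_that("forward log-likelihood matches enumeration and closed forms", {
  set.seed(101)
  for (i in 1:20) {
    T <- sample(2:6, 1); K <- sample(2:3, 1)
    toy <- random_toy_hmm(T, K)
    ll <- statesync:::forward_loglik_cpp(toy$logB, toy$trans, toy$init, 1L,
                                         as.integer(T))
    expect_equal(ll, enumerate_hmm(toy$logB, toy$trans, toy$init)$loglik,
                 tolerance = 1e-10)
  }
  # emission probabilities independent of state: reduces to i.i.d. Gaussian
  set.seed(102)
  x <- matrix(rnorm(30), 30, 1)
  fit <- list(K = 2, means = matrix(0, 2, 1),
              covs = array(1, c(1, 1, 2)),
              transmat = matrix(0.5, 2, 2), initial = c(0.5, 0.5))
  class(fit) <- "HmmFit"
  expect_equal(log_likelihood(fit, x), sum(dnorm(x, log = TRUE)),
               tolerance = 1e-10)
  # independence across subject-boundary resets: LL doubles on duplication
  tm <- make_truth(K = 2, R = 2, separation = 3, seed = 1)
  sim <- simulate_cohort(tm, c(1, 1), T = 50, seed = 2)
  f <- fit_hmm(sim$cohort, K = 2, n_restarts = 1, seed = 3, max_iter = 20)
  one <- log_likelihood(f, sim$cohort$data[[1]])
  both <- statesync:::forward_loglik_cpp(
    statesync:::gaussian_logdens(rbind(sim$cohort$data[[1]],
                                       sim$cohort$data[[1]]),
                                 f$means, f$covs),
    f$transmat, f$initial, c(1L, 51L), c(50L, 100L))
  expect_equal(both, 2 * one, tolerance = 1e-8)
  expect_error(log_likelihood(f, matrix(0, 10, 5)), "regions")
})

test_that("Viterbi decoding matches exhaustive search and stated tie-breaks", {
  set.seed(103)
  for (i in 1:20) {
    T <- sample(2:6, 1); K <- sample(2:3, 1)
    toy <- random_toy_hmm(T, K)
    path <- statesync:::viterbi_cpp(toy$logB, log(toy$trans), log(toy$init))
    expect_equal(path, unname(enumerate_hmm(toy$logB, toy$trans,
                                            toy$init)$best_path))
  }
  # exact tie between all paths: lexicographically smallest wins
  logB <- matrix(0, 4, 2)
  trans <- matrix(0.5, 2, 2)
  path <- statesync:::viterbi_cpp(logB, log(trans), log(c(0.5, 0.5)))
  expect_equal(path, rep(1L, 4))
  # perfectly separated emissions: per-volume nearest-state assignment
  tm <- make_truth(K = 3, R = 3, separation = 30, seed = 4)
  sim <- simulate_cohort(tm, c(2, 2), T = 80, seed = 5)
  fit <- list(K = 3, means = tm$state_means, covs = tm$state_covs,
              transmat = tm$transmat, initial = tm$initial)
  class(fit) <- "HmmFit"
  for (m in sim$cohort$data) {
    d <- as.matrix(dist(rbind(m, tm$state_means)))
    d <- d[seq_len(nrow(m)), nrow(m) + 1:3, drop = FALSE]
    expect_equal(viterbi_path(fit, m), unname(apply(d, 1, which.min)))
  }
})

test_that("EM fits are monotone, seeded, and recover a small truth model", {
  tm <- make_truth(K = 3, R = 5, separation = 5, seed = 21)
  sim <- simulate_cohort(tm, c(5, 5), T = 500, seed = 22)
  f1 <- fit_hmm(sim$cohort, K = 3, n_restarts = 2, seed = 23, max_iter = 100)
  f2 <- fit_hmm(sim$cohort, K = 3, n_restarts = 2, seed = 23, max_iter = 100)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$transmat, f2$transmat)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  expect_equal(rowSums(f1$transmat), rep(1, 3), tolerance = 1e-10)
  expect_equal(f1$n_params, (3 - 1) + 3 * 2 + 3 * 5 + 3 * 15)
  dec <- decode_cohort(f1, sim$cohort)
  perm <- align_states(f1, tm, paths = dec, ref_paths = sim$paths)
  expect_gt(path_agreement(dec, sim$paths, perm), 0.95)
  expect_lt(max(abs(align_transmat(f1$transmat, perm) - tm$transmat)), 0.05)
})

test_that("AIC follows its formula and selects the generating state count", {
  tm <- make_truth(K = 3, R = 4, separation = 5, seed = 31)
  sim <- simulate_cohort(tm, c(4, 4), T = 300, seed = 32)
  f0 <- fit_hmm(sim$cohort, K = 2, n_restarts = 1, seed = 30, max_iter = 20)
  ll_total <- sum(vapply(sim$cohort$data,
                         function(m) log_likelihood(f0, m), 0))
  expect_equal(aic_hmm(f0, sim$cohort), 2 * f0$n_params - 2 * ll_total,
               tolerance = 1e-8)
  sel <- select_k(sim$cohort, k_range = 2:5, n_restarts = 1, seed = 33,
                  max_iter = 50, cov_type = "diagonal")
  expect_equal(sel$best_k, 3)
  expect_equal(nrow(sel$table), 4L)
  # AIC strictly increases in n_params at equal log-likelihood
  expect_true(all(diff(sel$table$n_params) > 0))
  ll_fixed <- -500
  aics <- 2 * sel$table$n_params - 2 * ll_fixed
  expect_true(all(diff(aics) > 0))
  # length-one scan returns that K
  sel1 <- select_k(sim$cohort, k_range = 4, n_restarts = 1, seed = 33,
                   max_iter = 20, cov_type = "diagonal")
  expect_equal(sel1$best_k, 4)
})

test_that("state alignment solves the assignment problem exactly", {
  # identity: aligning a model with itself
  tm <- make_truth(K = 4, R = 3, separation = 4, seed = 41)
  fit <- list(K = 4, means = tm$state_means, covs = tm$state_covs,
              transmat = tm$transmat, initial = tm$initial)
  class(fit) <- "HmmFit"
  expect_equal(align_states(fit, tm), 1:4)
  # permuted copy recovers the inverse permutation
  prm <- c(3L, 1L, 4L, 2L)
  fitp <- fit
  fitp$means <- tm$state_means[prm, ]
  expect_equal(align_states(fitp, tm), prm)
  expect_error(align_states(fit, make_truth(K = 3, R = 3, separation = 4)),
               "different K")
  # assignment solver agrees with brute force on random costs
  set.seed(42)
  perms4 <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms4 <- perms4[apply(perms4, 1, function(p) length(unique(p)) == 4), ]
  for (i in 1:20) {
    cost <- matrix(runif(16), 4, 4)
    p <- statesync:::solve_assignment(cost)
    vals <- apply(perms4, 1, function(q) sum(cost[cbind(1:4, q)]))
    expect_equal(sum(cost[cbind(1:4, p)]), min(vals), tolerance = 1e-12)
  }
})

test_that("fits serialise to JSON and back", {
  tm <- make_truth(K = 2, R = 3, separation = 4, seed = 51)
  sim <- simulate_cohort(tm, c(2, 2), T = 100, seed = 52)
  fit <- fit_hmm(sim$cohort, K = 2, n_restarts = 1, seed = 53, max_iter = 30)
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_fit(fit, f)
  back <- read_hmm_fit(f)
  expect_equal(back$means, fit$means, tolerance = 1e-12)
  expect_equal(back$transmat, fit$transmat, tolerance = 1e-12)
  expect_equal(back$covs, fit$covs, tolerance = 1e-12)
  expect_equal(log_likelihood(back, sim$cohort$data[[1]]),
               log_likelihood(fit, sim$cohort$data[[1]]), tolerance = 1e-8)
})
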