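# Independent oracles used across the suite. These deliberately avoid the
# package's own forward/Viterbi/adjustment code paths.

# Exhaustive-path log-likelihood and best path of a Gaussian-free HMM
# specified by emission log-densities. Paths are enumerated in lexicographic
# order so the first maximiser is the lexicographically smallest.
enumerate_hmm <- function(logB, trans, init) {
  T <- nrow(logB); K <- ncol(logB)
  grid <- expand.grid(rep(list(seq_len(K)), T))
  paths <- as.matrix(grid)[, rev(seq_len(T)), drop = FALSE]
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  lp <- log(init)[paths[, 1L]] + logB[cbind(1L, paths[, 1L])]
  if (T > 1L) for (t in 2:T)
    lp <- lp + log(trans)[cbind(paths[, t - 1L], paths[, t])] +
      logB[cbind(t, paths[, t])]
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = paths[which.max(lp), ])
}

# Literal Benjamini-Hochberg step-up procedure.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Brute-force max-|t| permutation FWE over an explicitly enumerated label
# space, using t.test() as the statistic oracle.
fwe_bruteforce <- function(values, labels) {
  g <- as.factor(labels)
  n1 <- sum(g == levels(g)[1L])
  combs <- utils::combn(length(g), n1)
  tstat <- function(lab) {
    vapply(seq_len(ncol(values)), function(j) {
      a <- values[lab == levels(g)[1L], j]
      b <- values[lab != levels(g)[1L], j]
      unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
    }, 0)
  }
  obs <- tstat(as.character(g))
  max_null <- apply(combs, 2L, function(idx) {
    lab <- rep(levels(g)[2L], length(g))
    lab[idx] <- levels(g)[1L]
    max(abs(tstat(lab)))
  })
  list(t = obs,
       p_fwe = vapply(abs(obs), function(a) mean(max_null >= a - 1e-12), 0))
}

# Apply a state permutation (fitted k -> reference perm[k]) to a fitted
# transition matrix so it is comparable to the reference matrix.
align_transmat <- function(transmat, perm) {
  K <- nrow(transmat)
  P <- matrix(0, K, K)
  for (k in seq_len(K)) P[k, perm[k]] <- 1
  t(P) %*% transmat %*% P
}

# Proportion of decoded volumes agreeing with the truth after relabelling.
path_agreement <- function(decoded, truth, perm) {
  mean(unlist(relabel_paths(decoded, perm)$paths) == unlist(truth$paths))
}

random_toy_hmm <- function(T, K) {
  trans <- matrix(stats::rexp(K * K), K, K)
  trans <- trans / rowSums(trans)
  init <- stats::rexp(K); init <- init / sum(init)
  logB <- matrix(stats::rnorm(T * K), T, K)
  list(logB = logB, trans = trans, init = init)
}
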