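#' Construct a set of per-subject state paths
#'
#' @param paths named list of integer vectors (states in `1..K`), equal
#'   lengths.
#' @param K number of states.
#' @return an object of class `StatePathSet`.
#' @export
state_path_set <- function(paths, K) {
  stopifnot(is.list(paths), length(paths) >= 1L)
  lens <- vapply(paths, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("all state paths must have equal length")
  rng <- range(unlist(paths))
  if (rng[1L] < 1L || rng[2L] > K)
    stop("state indices must lie in 1..K")
  structure(list(paths = lapply(paths, as.integer), K = as.integer(K),
                 subject_ids = names(paths)),
            class = "StatePathSet")
}

#' @export
print.StatePathSet <- function(x, ...) {
  cat(sprintf("StatePathSet: %d subjects, T = %d, K = %d\n",
              length(x$paths), length(x$paths[[1L]]), x$K))
  invisible(x)
}

# Per-state Gaussian log-densities for a T x R data matrix.
# covs: R x R x K array. Returns T x K.
gaussian_logdens <- function(X, means, covs) {
  T <- nrow(X); R <- ncol(X); K <- nrow(means)
  out <- matrix(0, T, K)
  for (k in seq_len(K)) {
    U <- chol(covs[, , k])
    logdet <- 2 * sum(log(diag(U)))
    Xc <- sweep(X, 2L, means[k, ])
    Z <- Xc %*% backsolve(U, diag(R))
    out[, k] <- -0.5 * (R * log(2 * pi) + logdet + rowSums(Z * Z))
  }
  out
}

# Ensure a covariance update stays positive-definite; ridge of
# 1e-6 * mean variance added when a Cholesky factorisation fails.
regularise_cov <- function(S) {
  S <- (S + t(S)) / 2
  ok <- !inherits(try(chol(S), silent = TRUE), "try-error")
  if (ok) return(S)
  ridge <- 1e-6 * mean(diag(S))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-6
  for (i in 1:30) {
    S2 <- S + diag(ridge, nrow(S))
    if (!inherits(try(chol(S2), silent = TRUE), "try-error")) return(S2)
    ridge <- ridge * 10
  }
  stop("degenerate fit: covariance update could not be regularised")
}

hmm_n_params <- function(K, R, cov_type) {
  emis <- switch(cov_type,
                 full = K * R * (R + 1) / 2,
                 diagonal = K * R,
                 shared = R * (R + 1) / 2)
  (K - 1) + K * (K - 1) + K * R + emis
}

#' Fit a Gaussian-observation hidden Markov model to a cohort
#'
#' Runs EM (Baum-Welch) on the concatenation of all subjects' series.
#' Forward-backward recursions reset at subject boundaries with the shared
#' initial distribution, so concatenation never creates spurious transitions.
#' Each restart is initialised from a seeded k-means partition of the pooled
#' volumes; the restart with the best final log-likelihood wins, ties broken
#' by restart order.
#'
#' @param cohort a `CohortSeries` (or a plain list of T x R matrices).
#' @param K number of states (>= 2).
#' @param max_iter EM iteration cap (default 500 training cycles).
#' @param tol convergence threshold on the per-volume log-likelihood change.
#' @param n_restarts number of seeded k-means restarts (default 5).
#' @param seed base RNG seed; restart `r` uses `seed + r - 1`.
#' @param cov_type `"full"` (default), `"diagonal"`, or `"shared"` state
#'   covariances.
#' @return an object of class `HmmFit` with fields `K`, `means`, `covs`,
#'   `transmat`, `initial`, `loglik_trace`, `loglik`, `n_params`,
#'   `converged`, `cov_type`, `seed`, `restart`.
#' @export
fit_hmm <- function(cohort, K, max_iter = 500L, tol = 1e-4, n_restarts = 5L,
                    seed = 1L, cov_type = c("full", "diagonal", "shared")) {
  cov_type <- match.arg(cov_type)
  mats <- if (inherits(cohort, "CohortSeries")) cohort$data else cohort
  stopifnot(K >= 2, length(mats) >= 1L)
  Tn <- vapply(mats, nrow, 0L)
  X <- do.call(rbind, mats)
  R <- ncol(X)
  if (nrow(X) < 5 * K * R)
    warning("few volumes (", nrow(X), ") relative to K*R = ", K * R,
            "; fit may be unstable")
  seg_ends <- cumsum(Tn)
  seg_starts <- c(1L, utils::head(seg_ends, -1L) + 1L)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    old <- .Random.seed_save()
    set.seed(seed + r - 1L)
    fit <- tryCatch(
      em_once(X, K, seg_starts, seg_ends, max_iter, tol, cov_type),
      error = function(e) e)
    .Random.seed_restore(old)
    if (inherits(fit, "error")) {
      if (r == n_restarts && is.null(best)) stop(conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart <- r
    }
  }
  best$seed <- seed
  best$n_params <- hmm_n_params(K, R, cov_type)
  best$region_ids <- colnames(X)
  class(best) <- "HmmFit"
  best
}

# One EM run from a k-means initialisation (uses the current RNG state).
# k-means runs on a subsample of at most 20000 volumes with 10 independent
# starts, which locates well-separated centroids far more reliably than a
# single full-data start; all volumes are then assigned to the nearest
# centroid for the covariance initialisation.
em_once <- function(X, K, seg_starts, seg_ends, max_iter, tol, cov_type) {
  T_all <- nrow(X); R <- ncol(X)
  idx <- if (T_all > 20000L) sample.int(T_all, 20000L) else seq_len(T_all)
  km <- suppressWarnings(
    stats::kmeans(X[idx, , drop = FALSE], centers = K, nstart = 10L,
                  iter.max = 50L))
  means <- km$centers
  d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(means) +
    outer(rep(1, T_all), rowSums(means^2))
  cl <- max.col(-d2, ties.method = "first")
  covs <- array(0, c(R, R, K))
  for (k in seq_len(K)) {
    at <- cl == k
    S <- if (sum(at) > R) stats::cov(X[at, , drop = FALSE]) else diag(R)
    covs[, , k] <- regularise_cov(shape_cov(S, cov_type, NULL))
  }
  transmat <- matrix(0.1 / (K - 1), K, K); diag(transmat) <- 0.9
  initial <- rep(1 / K, K)

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- gaussian_logdens(X, means, covs)
    es <- forward_backward_cpp(logB, transmat, initial, seg_starts, seg_ends)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_prev) &&
        (es$loglik - ll_prev) / T_all < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    g <- es$gamma
    Nk <- colSums(g)
    means <- crossprod(g, X) / Nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, means[k, ])
      S <- crossprod(Xc * g[, k], Xc) / Nk[k]
      covs[, , k] <- regularise_cov(shape_cov(S, cov_type, NULL))
    }
    if (cov_type == "shared") {
      S <- matrix(0, R, R)
      for (k in seq_len(K)) S <- S + covs[, , k] * Nk[k]
      S <- regularise_cov(S / sum(Nk))
      for (k in seq_len(K)) covs[, , k] <- S
    }
    xi <- es$xi
    rs <- rowSums(xi)
    transmat <- xi / ifelse(rs > 0, rs, 1)
    transmat[rs == 0, ] <- 1 / K
    initial <- es$init_counts / sum(es$init_counts)
  }
  list(K = K, means = unname(means), covs = covs, transmat = unname(transmat),
       initial = as.numeric(initial), loglik_trace = trace,
       loglik = trace[length(trace)], converged = converged,
       cov_type = cov_type)
}

shape_cov <- function(S, cov_type, ...) {
  if (cov_type == "diagonal") diag(diag(S), nrow(S)) else S
}

#' @export
print.HmmFit <- function(x, ...) {
  cat(sprintf("HmmFit: K = %d states, %d regions, %s covariance\n",
              x$K, ncol(x$means), x$cov_type))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, length(x$loglik_trace),
              if (isTRUE(x$converged)) "converged" else "iteration cap"))
  invisible(x)
}

#' Forward-algorithm log-likelihood of one subject's series
#'
#' @param fit an `HmmFit`.
#' @param series T x R numeric matrix.
#' @return exact log-likelihood (scalar).
#' @export
log_likelihood <- function(fit, series) {
  series <- as.matrix(series)
  if (ncol(series) != ncol(fit$means))
    stop("series has ", ncol(series), " regions; model expects ",
         ncol(fit$means))
  logB <- gaussian_logdens(series, fit$means, fit$covs)
  forward_loglik_cpp(logB, fit$transmat, fit$initial, 1L, nrow(series))
}

#' Akaike information criterion of a fitted HMM on a cohort
#'
#' `AIC = 2 * n_params - 2 * total log-likelihood`, the total taken over all
#' subjects with forward-backward resets at subject boundaries.
#'
#' @param fit an `HmmFit`.
#' @param cohort a `CohortSeries` or list of matrices.
#' @return the AIC (scalar).
#' @export
aic_hmm <- function(fit, cohort) {
  mats <- if (inherits(cohort, "CohortSeries")) cohort$data else cohort
  ll <- sum(vapply(mats, function(m) log_likelihood(fit, m), 0))
  2 * fit$n_params - 2 * ll
}

#' Scan candidate state counts and select by AIC
#'
#' Fits each K in `k_range` with the shared restart protocol and returns the
#' AIC-minimising model order plus the full table.
#'
#' @inheritParams fit_hmm
#' @param k_range integer vector of candidate state counts.
#' @return list with `best_k`, `table` (data frame K, loglik, n_params, aic),
#'   and `fits` (per-K `HmmFit`s).
#' @export
select_k <- function(cohort, k_range, max_iter = 500L, tol = 1e-4,
                     n_restarts = 5L, seed = 1L,
                     cov_type = c("full", "diagonal", "shared")) {
  cov_type <- match.arg(cov_type)
  stopifnot(length(k_range) >= 1L)
  fits <- lapply(k_range, function(K)
    tryCatch(fit_hmm(cohort, K, max_iter, tol, n_restarts, seed, cov_type),
             error = function(e)
               stop("fit failed at K = ", K, ": ", conditionMessage(e))))
  aics <- vapply(fits, function(f) aic_hmm(f, cohort), 0)
  tab <- data.frame(K = k_range,
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    n_params = vapply(fits, function(f) f$n_params, 0),
                    aic = aics)
  list(best_k = k_range[which.min(aics)], table = tab, fits = fits)
}

#' Viterbi-decode one subject's series
#'
#' Maximum a-posteriori state path by log-domain dynamic programming; ties
#' resolved toward the lowest state index.
#'
#' @param fit an `HmmFit`.
#' @param series T x R numeric matrix.
#' @return integer state path (values in `1..K`).
#' @export
viterbi_path <- function(fit, series) {
  series <- as.matrix(series)
  if (ncol(series) != ncol(fit$means))
    stop("series has ", ncol(series), " regions; model expects ",
         ncol(fit$means))
  logB <- gaussian_logdens(series, fit$means, fit$covs)
  with_log <- function(p) ifelse(p > 0, log(p), -Inf)
  viterbi_cpp(logB, with_log(fit$transmat), with_log(fit$initial))
}

#' Viterbi-decode every subject in a cohort
#'
#' @param fit an `HmmFit`.
#' @param cohort a `CohortSeries`.
#' @return a `StatePathSet` in cohort subject order.
#' @export
decode_cohort <- function(fit, cohort) {
  mats <- if (inherits(cohort, "CohortSeries")) cohort$data else cohort
  paths <- lapply(mats, function(m) viterbi_path(fit, m))
  state_path_set(paths, K = fit$K)
}

# Exact solution of the assignment problem (Hungarian algorithm,
# shortest-augmenting-path form). cost: square matrix; returns a permutation
# p with p[i] = column assigned to row i, minimising total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

#' Resolve label switching between a fit and a reference model
#'
#' Finds the state permutation maximising agreement with a reference. When
#' both decoded and reference paths are supplied, the optimal assignment is
#' computed on their confusion matrix; otherwise on the Euclidean distance
#' matrix between state means.
#'
#' @param fit an `HmmFit`.
#' @param reference a `TruthModel` or another `HmmFit`.
#' @param paths,ref_paths optional `StatePathSet`s (decoded and true) for
#'   confusion-based alignment.
#' @return integer permutation `perm` such that fitted state `k` corresponds
#'   to reference state `perm[k]`.
#' @export
align_states <- function(fit, reference, paths = NULL, ref_paths = NULL) {
  K <- fit$K
  ref_K <- if (!is.null(reference$K)) reference$K else nrow(reference$state_means)
  if (K != ref_K) stop("cannot align models with different K (", K, " vs ",
                       ref_K, ")")
  if (!is.null(paths) && !is.null(ref_paths)) {
    a <- unlist(paths$paths); b <- unlist(ref_paths$paths)
    conf <- table(factor(a, levels = seq_len(K)),
                  factor(b, levels = seq_len(K)))
    cost <- -as.matrix(conf)
  } else {
    ref_means <- if (!is.null(reference$state_means)) reference$state_means
                 else reference$means
    cost <- as.matrix(stats::dist(rbind(fit$means, ref_means)))
    cost <- cost[seq_len(K), K + seq_len(K), drop = FALSE]
  }
  solve_assignment(cost)
}

#' Relabel a state path set by a permutation
#' @param paths a `StatePathSet`.
#' @param perm permutation from [align_states()].
#' @return relabelled `StatePathSet`.
#' @export
relabel_paths <- function(paths, perm) {
  state_path_set(lapply(paths$paths, function(p) perm[p]), K = paths$K)
}

#' Serialise a fitted HMM to JSON
#' @param fit an `HmmFit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hmm_fit <- function(fit, path) {
  obj <- fit
  obj$covs <- lapply(seq_len(fit$K), function(k) fit$covs[, , k])
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted HMM from JSON
#' @param path file written by [write_hmm_fit()].
#' @return an `HmmFit`.
#' @export
read_hmm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- ncol(obj$means)
  covs <- array(0, c(R, R, obj$K))
  for (k in seq_len(obj$K)) {
    covs[, , k] <- if (is.list(obj$covs)) obj$covs[[k]] else obj$covs[k, , ]
  }
  obj$covs <- covs
  class(obj) <- "HmmFit"
  obj
}
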