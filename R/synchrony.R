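# Windowed state-presence indicator for one path: T x K logical-as-numeric
# matrix where entry (v, k) is 1 iff the path visits state k anywhere in
# volumes [v - w, v + w] (edge windows truncated). Computed via cumulative
# sums of the one-hot path.
window_presence <- function(path, K, w) {
  T <- length(path)
  onehot <- matrix(0, T, K)
  onehot[cbind(seq_len(T), path)] <- 1
  if (w == 0L) return(onehot)
  cs <- rbind(0, apply(onehot, 2L, cumsum))
  lo <- pmax(seq_len(T) - w, 1L)
  hi <- pmin(seq_len(T) + w, T)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) > 0
}

# Stack presence indicators for all subjects: S x (T*K) matrix (column-major
# over T then K), so any pseudo-group curve is a column mean over a row
# subset.
presence_stack <- function(paths, w) {
  K <- paths$K
  t(vapply(paths$paths, function(p)
    as.numeric(window_presence(p, K, w)),
    numeric(length(paths$paths[[1L]]) * K)))
}

#' Windowed inter-subject brain-state consistency
#'
#' For each state `k` and volume `v`, the percentage of member subjects whose
#' state path visits `k` anywhere in the sliding window `[v - w, v + w]`
#' (default half-width 3 TRs, a 7-TR window; edge windows truncated). Scores
#' run from 0 (no subject expresses the state) to 100 (the state is present
#' in all subjects).
#'
#' @param paths a `StatePathSet`.
#' @param members subject ids or indices forming the group (default all).
#' @param w window half-width in volumes (default 3).
#' @return an object of class `ConsistencyCurve`: list with `value`
#'   (K x T percentage matrix), `w`, `n_members`, `members`.
#' @export
windowed_consistency <- function(paths, members = NULL, w = 3L) {
  stopifnot(w >= 0L)
  if (is.null(members)) members <- seq_along(paths$paths)
  if (is.character(members))
    members <- match(members, paths$subject_ids)
  if (!length(members) || anyNA(members))
    stop("empty or unknown member set")
  K <- paths$K
  T <- length(paths$paths[[1L]])
  acc <- matrix(0, T, K)
  for (i in members) acc <- acc + window_presence(paths$paths[[i]], K, w)
  structure(list(value = t(acc) / length(members) * 100, w = as.integer(w),
                 n_members = length(members), members = members),
            class = "ConsistencyCurve")
}

#' @export
print.ConsistencyCurve <- function(x, ...) {
  cat(sprintf("ConsistencyCurve: %d states x %d volumes, window +/-%d TR, %d subjects\n",
              nrow(x$value), ncol(x$value), x$w, x$n_members))
  invisible(x)
}

#' Between-group resampling null for state consistency
#'
#' Each iteration splits the whole cohort, without replacement, into
#' pseudo-groups of the original group sizes and computes their consistency
#' curves, mixing members of both groups. The per-state, per-volume 95th
#' percentile across iterations is returned separately for each pseudo-group
#' size, giving the significance surface an observed group curve must exceed.
#'
#' @param paths a `StatePathSet` for the whole cohort.
#' @param sizes integer pair `(n_A, n_B)`; must sum to the cohort size.
#' @param n_iter resampling iterations (default 1000).
#' @param w window half-width (default 3).
#' @param seed RNG seed.
#' @param probs percentile of the null (default 0.95).
#' @return list with `threshold_A`, `threshold_B` (K x T matrices),
#'   `n_iter`, `sizes`, `seed`.
#' @export
between_group_null <- function(paths, sizes, n_iter = 1000L, w = 3L,
                               seed = 1L, probs = 0.95) {
  n <- length(paths$paths)
  if (sum(sizes) != n)
    stop("pseudo-group sizes must sum to the cohort size (", n, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  P <- presence_stack(paths, w)
  K <- paths$K
  T <- length(paths$paths[[1L]])
  null_A <- matrix(0, n_iter, T * K)
  null_B <- matrix(0, n_iter, T * K)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n)
    a <- idx[seq_len(sizes[1L])]
    b <- idx[seq.int(sizes[1L] + 1L, n)]
    null_A[it, ] <- colMeans(P[a, , drop = FALSE]) * 100
    null_B[it, ] <- colMeans(P[b, , drop = FALSE]) * 100
  }
  q <- function(M) t(matrix(apply(M, 2L, stats::quantile, probs = probs,
                                  names = FALSE), T, K))
  list(threshold_A = q(null_A), threshold_B = q(null_B),
       n_iter = n_iter, sizes = sizes, seed = seed, w = w, probs = probs)
}

#' Within-group surrogate-chain null for state consistency
#'
#' Surrogate Viterbi paths are simulated for every group member from the
#' group's empirical transition matrix (pooled masked transition counts of
#' the decoded paths) with a uniformly random initial state, destroying
#' cross-subject temporal alignment while preserving switching statistics.
#' Each iteration computes the surrogate set's windowed consistency and
#' averages it over volumes per state; the per-state 95th percentile across
#' iterations is the within-group significance level.
#'
#' @param group_paths a `StatePathSet` for one group (>= 2 subjects).
#' @param n_iter surrogate iterations (default 1000).
#' @param w window half-width (default 3).
#' @param mask optional mask used when estimating the transition matrix.
#' @param seed RNG seed.
#' @param probs percentile of the null (default 0.95).
#' @param transmat optional transition matrix overriding the group-empirical
#'   estimate (e.g. the joint HMM fit's matrix).
#' @param initial `"uniform"` (default) or `"stationary"` surrogate initial
#'   state distribution.
#' @param pooled if `TRUE`, also return a single threshold pooled across
#'   states.
#' @return list with `threshold` (per-state numeric vector), `null`
#'   (n_iter x K matrix of null means), `transmat`, and optionally
#'   `threshold_pooled`.
#' @export
within_group_null <- function(group_paths, n_iter = 1000L, w = 3L,
                              mask = NULL, seed = 1L, probs = 0.95,
                              transmat = NULL,
                              initial = c("uniform", "stationary"),
                              pooled = FALSE) {
  initial <- match.arg(initial)
  n <- length(group_paths$paths)
  if (n < 2L) stop("within-group null needs at least 2 subjects")
  K <- group_paths$K
  T <- length(group_paths$paths[[1L]])
  if (is.null(transmat)) transmat <- pooled_transmat(group_paths, mask)
  init <- if (initial == "uniform") rep(1 / K, K) else {
    e <- abs(Re(eigen(t(transmat))$vectors[, 1L]))
    e / sum(e)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_means <- matrix(0, n_iter, K)
  for (it in seq_len(n_iter)) {
    sur <- sim_markov_cpp(transmat, init, T, n)
    acc <- matrix(0, T, K)
    for (i in seq_len(n)) acc <- acc + window_presence(sur[, i], K, w)
    null_means[it, ] <- colMeans(acc / n * 100)
  }
  thr <- apply(null_means, 2L, stats::quantile, probs = probs, names = FALSE)
  out <- list(threshold = thr, null = null_means, transmat = transmat,
              n_iter = n_iter, seed = seed, w = w, probs = probs)
  if (pooled)
    out$threshold_pooled <- stats::quantile(as.numeric(null_means),
                                            probs = probs, names = FALSE)
  out
}

#' Flag supra-threshold synchrony events
#'
#' Flags masked volumes where a group's consistency exceeds both the
#' between-group surface and the within-group per-state level, then emits
#' contiguous flagged runs of at least `min_run` volumes as events, ranked
#' by duration.
#'
#' @param curve a [windowed_consistency()] result for the observed group.
#' @param between K x T between-group threshold surface for this group's
#'   size (e.g. `threshold_A` from [between_group_null()]).
#' @param within per-state within-group thresholds (from
#'   [within_group_null()]).
#' @param mask logical per-volume mask restricting flagging (default all).
#' @param min_run minimum run length in volumes (default 1).
#' @return data frame with `state`, `start`, `end` (1-based volume indices,
#'   inclusive), `duration`, `peak` (peak consistency, percent), sorted by
#'   decreasing duration.
#' @export
flag_sync_events <- function(curve, between, within, mask = NULL,
                             min_run = 1L) {
  val <- curve$value
  K <- nrow(val); T <- ncol(val)
  stopifnot(all(dim(between) == c(K, T)), length(within) == K)
  if (is.null(mask)) mask <- rep(TRUE, T)
  stopifnot(length(mask) == T)
  events <- list()
  for (k in seq_len(K)) {
    flag <- mask & (val[k, ] > between[k, ]) & (val[k, ] > within[k])
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    for (i in which(keep)) {
      events[[length(events) + 1L]] <- data.frame(
        state = k, start = starts[i], end = ends[i],
        duration = r$lengths[i],
        peak = max(val[k, starts[i]:ends[i]]))
    }
  }
  if (!length(events))
    return(data.frame(state = integer(), start = integer(), end = integer(),
                      duration = integer(), peak = numeric()))
  out <- do.call(rbind, events)
  out <- out[order(-out$duration, out$state, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full synchrony analysis for both groups
#'
#' Convenience wrapper: computes observed group consistency curves, the
#' between-group resampling null, per-group within-group surrogate nulls,
#' and the flagged events inside the positive-scene mask.
#'
#' @param paths cohort `StatePathSet`.
#' @param group_labels two-level labels in subject order.
#' @param mask logical per-volume epoch mask.
#' @param n_iter null iterations (default 1000).
#' @param w window half-width (default 3).
#' @param seed RNG seed.
#' @param min_run minimum event run length.
#' @return list with per-group `curve`, `within`, shared `between`, and
#'   per-group `events` data frames.
#' @export
synchrony_analysis <- function(paths, group_labels, mask, n_iter = 1000L,
                               w = 3L, seed = 1L, min_run = 1L) {
  g <- as.factor(group_labels)
  stopifnot(nlevels(g) == 2L)
  lev <- levels(g)
  idx_A <- which(g == lev[1L]); idx_B <- which(g == lev[2L])
  curve_A <- windowed_consistency(paths, idx_A, w)
  curve_B <- windowed_consistency(paths, idx_B, w)
  btw <- between_group_null(paths, c(length(idx_A), length(idx_B)),
                            n_iter = n_iter, w = w, seed = seed)
  sub_paths <- function(idx) state_path_set(paths$paths[idx], K = paths$K)
  win_A <- within_group_null(sub_paths(idx_A), n_iter = n_iter, w = w,
                             mask = mask, seed = seed + 1L)
  win_B <- within_group_null(sub_paths(idx_B), n_iter = n_iter, w = w,
                             mask = mask, seed = seed + 2L)
  list(
    groups = lev,
    curve = stats::setNames(list(curve_A, curve_B), lev),
    between = btw,
    within = stats::setNames(list(win_A, win_B), lev),
    events = stats::setNames(list(
      flag_sync_events(curve_A, btw$threshold_A, win_A$threshold, mask,
                       min_run),
      flag_sync_events(curve_B, btw$threshold_B, win_B$threshold, mask,
                       min_run)), lev))
}
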