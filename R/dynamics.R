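# Split a logical mask into maximal contiguous TRUE segments (list of index
# vectors). Dwell and transition statistics truncate at these boundaries.
mask_segments <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  breaks <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(breaks) - 1L), function(i)
    idx[(breaks[i] + 1L):breaks[i + 1L]])
}

#' Fractional occupancy per subject and state over masked volumes
#'
#' Entry `(s, k)` is the share of masked volumes subject `s` spends in state
#' `k`; rows sum to one.
#'
#' @param paths a `StatePathSet`.
#' @param mask logical per-volume mask (default all volumes).
#' @return subjects x states matrix.
#' @export
fractional_occupancy <- function(paths, mask = NULL) {
  T <- length(paths$paths[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, T)
  stopifnot(length(mask) == T)
  if (!any(mask)) stop("mask selects no volumes")
  occ <- t(vapply(paths$paths, function(p)
    tabulate(p[mask], nbins = paths$K) / sum(mask), numeric(paths$K)))
  dimnames(occ) <- list(paths$subject_ids, paste0("state", seq_len(paths$K)))
  occ
}

#' Mean dwell time per subject and state
#'
#' A visit is a maximal run of one state within a contiguous masked segment
#' (runs are truncated at mask boundaries). Mean visit duration is reported
#' in seconds (`run length * tr_seconds`); states never visited are `NA`.
#'
#' @inheritParams fractional_occupancy
#' @param tr_seconds repetition time in seconds.
#' @return list with `mean_dwell_s` (subjects x states, `NA` when unvisited)
#'   and `n_visits` (subjects x states integer matrix).
#' @export
dwell_times <- function(paths, mask = NULL, tr_seconds = 0.81) {
  T <- length(paths$paths[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, T)
  stopifnot(length(mask) == T)
  segs <- mask_segments(mask)
  K <- paths$K
  n <- length(paths$paths)
  dwell <- matrix(NA_real_, n, K)
  visits <- matrix(0L, n, K)
  for (s in seq_len(n)) {
    tot_len <- numeric(K)
    for (seg in segs) {
      r <- rle(paths$paths[[s]][seg])
      for (k in seq_len(K)) {
        at <- r$values == k
        visits[s, k] <- visits[s, k] + sum(at)
        tot_len[k] <- tot_len[k] + sum(r$lengths[at])
      }
    }
    seen <- visits[s, ] > 0L
    dwell[s, seen] <- tot_len[seen] / visits[s, seen] * tr_seconds
  }
  dimnames(dwell) <- dimnames(visits) <-
    list(paths$subject_ids, paste0("state", seq_len(K)))
  list(mean_dwell_s = dwell, n_visits = visits)
}

#' Per-subject state transition probability matrices
#'
#' Counts transitions over consecutive masked volume pairs within contiguous
#' segments (a masked gap breaks the pair), then row-normalises. Rows with no
#' observed exits are left as absorbing (identity) rows and flagged.
#'
#' @inheritParams fractional_occupancy
#' @return list with `probs` (subjects x K x K array) and `undefined_rows`
#'   (subjects x K logical: rows with no observed transitions).
#' @export
transition_matrices <- function(paths, mask = NULL) {
  T <- length(paths$paths[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, T)
  stopifnot(length(mask) == T)
  segs <- mask_segments(mask)
  K <- paths$K
  n <- length(paths$paths)
  probs <- array(0, c(n, K, K))
  undef <- matrix(FALSE, n, K)
  for (s in seq_len(n)) {
    counts <- matrix(0, K, K)
    for (seg in segs) {
      p <- paths$paths[[s]][seg]
      if (length(p) < 2L) next
      from <- p[-length(p)]; to <- p[-1L]
      for (i in seq_along(from)) counts[from[i], to[i]] <-
          counts[from[i], to[i]] + 1
    }
    rs <- rowSums(counts)
    undef[s, ] <- rs == 0
    counts[rs == 0, ] <- diag(K)[rs == 0, , drop = FALSE]
    probs[s, , ] <- counts / rowSums(counts)
  }
  dimnames(undef) <- list(paths$subject_ids, paste0("state", seq_len(K)))
  list(probs = probs, undefined_rows = undef,
       subject_ids = paths$subject_ids)
}

# Pooled-count empirical transition matrix of a set of paths (used for the
# within-group surrogate null). Undefined rows fall back to self-transition.
pooled_transmat <- function(paths, mask = NULL) {
  T <- length(paths$paths[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, T)
  segs <- mask_segments(mask)
  K <- paths$K
  counts <- matrix(0, K, K)
  for (p in paths$paths) {
    for (seg in segs) {
      q <- p[seg]
      if (length(q) < 2L) next
      from <- q[-length(q)]; to <- q[-1L]
      for (i in seq_along(from)) counts[from[i], to[i]] <-
          counts[from[i], to[i]] + 1
    }
  }
  rs <- rowSums(counts)
  counts[rs == 0, ] <- diag(K)[rs == 0, , drop = FALSE]
  attr(counts, "undefined_rows") <- which(rs == 0)
  counts / rowSums(counts)
}

# Two-sample pooled-variance t statistics for each column of `values`
# (group A minus group B convention from the label factor's first level).
# Zero pooled variance yields NA.
col_tstats <- function(values, labels) {
  g <- as.factor(labels)
  stopifnot(nlevels(g) == 2L)
  a <- g == levels(g)[1L]
  n1 <- sum(a); n2 <- sum(!a)
  m1 <- colMeans(values[a, , drop = FALSE])
  m2 <- colMeans(values[!a, , drop = FALSE])
  v1 <- apply(values[a, , drop = FALSE], 2L, stats::var)
  v2 <- apply(values[!a, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 == 0] <- NA_real_
  t
}

# All label assignments when the permutation space is small enough to
# enumerate, otherwise `n_perm` random shuffles (always including the
# observed labelling).
perm_label_matrix <- function(labels, n_perm) {
  g <- as.factor(labels)
  n <- length(g)
  n1 <- sum(g == levels(g)[1L])
  n_splits <- choose(n, n1)
  if (n_splits <= n_perm) {
    combs <- utils::combn(n, n1)
    apply(combs, 2L, function(idx) {
      lab <- rep(levels(g)[2L], n)
      lab[idx] <- levels(g)[1L]
      lab
    })
  } else {
    cbind(as.character(g),
          replicate(n_perm - 1L, sample(as.character(g))))
  }
}

#' Group comparison with max-statistic permutation FWE correction
#'
#' Two-tailed unpaired pooled-variance t-test per feature; family-wise error
#' is controlled by referring each observed `|t|` to the permutation
#' distribution of the maximum `|t|` across features under group-label
#' shuffling. When the full permutation space is no larger than `n_perm` it
#' is enumerated exactly.
#'
#' @param values subjects x features numeric matrix.
#' @param labels two-level group labels (length = subjects).
#' @param n_perm permutation budget (default 5000).
#' @param seed RNG seed.
#' @return data frame with `feature`, `t`, `p_fwe` (`NA` t for zero-variance
#'   features).
#' @export
group_compare_fwe <- function(values, labels, n_perm = 5000L, seed = 1L) {
  values <- as.matrix(values)
  g <- as.factor(labels)
  if (min(table(g)) < 2L) stop("need at least 2 subjects per group")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs <- col_tstats(values, g)
  perms <- perm_label_matrix(g, n_perm)
  max_null <- apply(perms, 2L, function(lab) {
    t <- col_tstats(values, factor(lab, levels = levels(g)))
    if (all(is.na(t))) NA_real_ else max(abs(t), na.rm = TRUE)
  })
  max_null <- max_null[!is.na(max_null)]
  p_fwe <- vapply(abs(obs), function(a) {
    if (is.na(a)) return(NA_real_)
    mean(max_null >= a - 1e-12)
  }, 0)
  feats <- colnames(values)
  if (is.null(feats)) feats <- paste0("f", seq_along(obs))
  data.frame(feature = feats, t = as.numeric(obs), p_fwe = p_fwe,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network-based statistic on state transition probabilities
#'
#' Edge-wise two-sample t-tests on each directed transition probability
#' `k -> l`; edges with `|t|` above `t_thresh` form a directed graph whose
#' weakly connected components are scored by edge count. Family-wise error
#' is assessed against the permutation distribution of the maximal component
#' size under group-label shuffling.
#'
#' @param tset output of [transition_matrices()].
#' @param labels two-level group labels.
#' @param t_thresh edge-forming threshold on `|t|` (> 0).
#' @param n_perm permutation budget (default 5000).
#' @param seed RNG seed.
#' @return list with `components` (data frame: component id, n_edges, p_fwe),
#'   `edges` (data frame: from, to, t, component), and `max_null` (the
#'   permutation distribution). Empty data frames when nothing is
#'   supra-threshold.
#' @export
nbs_transitions <- function(tset, labels, t_thresh, n_perm = 5000L,
                            seed = 1L) {
  stopifnot(t_thresh > 0)
  probs <- tset$probs
  K <- dim(probs)[2L]
  n <- dim(probs)[1L]
  flat <- matrix(probs, n, K * K)  # column (l-1)*K + k  == edge k -> l
  g <- as.factor(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  comp_sizes <- function(tvec) {
    supra <- which(!is.na(tvec) & abs(tvec) > t_thresh)
    if (!length(supra)) return(list(sizes = integer(), membership = NULL,
                                    supra = supra))
    from <- (supra - 1L) %% K + 1L
    to <- (supra - 1L) %/% K + 1L
    gr <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to),
      directed = TRUE,
      vertices = data.frame(name = seq_len(K)))
    comp <- igraph::components(gr, mode = "weak")
    edge_comp <- comp$membership[as.character(from)]
    list(sizes = as.integer(table(edge_comp)), membership = edge_comp,
         supra = supra, from = from, to = to)
  }

  obs_t <- col_tstats(flat, g)
  obs <- comp_sizes(obs_t)
  perms <- perm_label_matrix(g, n_perm)
  max_null <- apply(perms, 2L, function(lab) {
    sz <- comp_sizes(col_tstats(flat, factor(lab, levels = levels(g))))$sizes
    if (length(sz)) max(sz) else 0L
  })
  if (!length(obs$supra)) {
    return(list(components = data.frame(component = integer(),
                                        n_edges = integer(),
                                        p_fwe = numeric()),
                edges = data.frame(from = integer(), to = integer(),
                                   t = numeric(), component = integer()),
                max_null = max_null))
  }
  comp_ids <- sort(unique(obs$membership))
  comp_tab <- data.frame(
    component = comp_ids,
    n_edges = vapply(comp_ids, function(cid)
      sum(obs$membership == cid), 0L),
    row.names = NULL)
  comp_tab$p_fwe <- vapply(comp_tab$n_edges, function(sz)
    mean(max_null >= sz), 0)
  edges <- data.frame(from = obs$from, to = obs$to,
                      t = obs_t[obs$supra],
                      component = as.integer(obs$membership),
                      row.names = NULL)
  list(components = comp_tab, edges = edges, max_null = max_null)
}
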