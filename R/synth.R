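#' Construct a ground-truth hidden Markov model for simulation
#'
#' Draws `K` Gaussian state centroids in `R` dimensions whose pairwise
#' Euclidean separation is at least `separation` (random directions, rescaled
#' once so the closest pair meets the margin), unit spherical covariances by
#' default, and a sticky row-stochastic transition matrix
#' (`p_stay` on the diagonal, the remainder spread uniformly).
#'
#' @param K number of states (>= 2).
#' @param R number of regions (>= 1).
#' @param separation minimum pairwise distance between state means.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param p_stay self-transition probability (default 0.85, giving dwell
#'   times of several volumes as seen in fMRI state models).
#' @param cov_scale marginal SD of the spherical state covariances.
#' @return an object of class `TruthModel` with fields `K`, `R`,
#'   `state_means` (K x R), `state_covs` (R x R x K), `transmat`, `initial`,
#'   `seed`.
#' @export
make_truth <- function(K, R, separation = 3, seed = 1L, p_stay = 0.85,
                       cov_scale = 1) {
  stopifnot(K >= 2, R >= 1, separation > 0, p_stay > 0, p_stay < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  means <- matrix(stats::rnorm(K * R), K, R)
  d <- stats::dist(means)
  if (min(d) < 1e-8)
    stop("degenerate draw: two state means coincide; try a different seed")
  means <- means * (separation / min(d))
  covs <- array(0, c(R, R, K))
  for (k in seq_len(K)) covs[, , k] <- diag(cov_scale^2, R)
  transmat <- matrix((1 - p_stay) / (K - 1), K, K)
  diag(transmat) <- p_stay
  structure(list(K = K, R = R, state_means = means, state_covs = covs,
                 transmat = transmat, initial = rep(1 / K, K), seed = seed),
            class = "TruthModel")
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Describe a planted synchrony episode
#'
#' During the given volume windows, each subject of the target group is forced
#' into `state` with probability `adherence` at every volume, emulating a
#' period of above-null synchronous state expression in one group.
#'
#' @param group group label the episode applies to.
#' @param state planted state index (1-based).
#' @param windows list of integer vectors `c(start, end)` (1-based, inclusive).
#' @param adherence per-volume forcing probability in `[0, 1]`.
#' @return a `PlantedSync` list.
#' @export
planted_sync <- function(group, state, windows, adherence = 1) {
  stopifnot(adherence >= 0, adherence <= 1)
  if (!is.list(windows)) windows <- list(windows)
  for (w in windows) stopifnot(length(w) == 2L, w[1L] >= 1L, w[2L] >= w[1L])
  structure(list(group = group, state = as.integer(state), windows = windows,
                 adherence = adherence), class = "PlantedSync")
}

#' Simulate a two-group cohort from a truth model
#'
#' Latent state paths follow the truth model's Markov chain except inside
#' planted windows, where subjects of the episode's group are forced into the
#' planted state with the episode's adherence probability (the chain then
#' continues from wherever the subject ends up). Observations are drawn from
#' the state-conditional Gaussians. True paths are returned for recovery
#' tests: planting acts on the latent path, not the emissions, so an HMM
#' fitted downstream genuinely has to recover the structure.
#'
#' @param truth a [make_truth()] model.
#' @param n_per_group integer pair `(n_A, n_B)`.
#' @param T number of volumes per subject.
#' @param planted list of [planted_sync()] episodes (default none).
#' @param seed RNG seed.
#' @param tr_seconds repetition time recorded on the cohort (default 0.81).
#' @return list with `cohort` (a `CohortSeries`) and `paths`
#'   (a `StatePathSet` of the true latent paths).
#' @export
simulate_cohort <- function(truth, n_per_group, T, planted = list(),
                            seed = 1L, tr_seconds = 0.81) {
  stopifnot(inherits(truth, "TruthModel"), length(n_per_group) == 2L)
  if (any(n_per_group < 1)) stop("both groups must have at least one subject")
  if (inherits(planted, "PlantedSync")) planted <- list(planted)
  for (p in planted) {
    if (max(vapply(p$windows, max, 0)) > T)
      stop("planted window extends beyond T = ", T)
    if (p$state > truth$K) stop("planted state exceeds K")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- sum(n_per_group)
  groups <- rep(c("A", "B"), n_per_group)
  ids <- sprintf("sub%02d", seq_len(n))
  chol_covs <- lapply(seq_len(truth$K),
                      function(k) chol(truth$state_covs[, , k]))
  paths <- vector("list", n)
  data <- vector("list", n)
  for (i in seq_len(n)) {
    force_state <- rep(NA_integer_, T)
    force_prob <- rep(0, T)
    for (p in planted) {
      if (p$group != groups[i]) next
      for (w in p$windows) {
        idx <- seq.int(w[1L], min(w[2L], T))
        force_state[idx] <- p$state
        force_prob[idx] <- p$adherence
      }
    }
    path <- integer(T)
    s <- sample.int(truth$K, 1L, prob = truth$initial)
    for (t in seq_len(T)) {
      if (t > 1L) s <- sample.int(truth$K, 1L, prob = truth$transmat[s, ])
      if (!is.na(force_state[t]) && force_prob[t] > 0 &&
          stats::runif(1L) < force_prob[t])
        s <- force_state[t]
      path[t] <- s
    }
    z <- matrix(stats::rnorm(T * truth$R), T, truth$R)
    x <- matrix(0, T, truth$R)
    for (k in seq_len(truth$K)) {
      at <- path == k
      if (!any(at)) next
      x[at, ] <- z[at, , drop = FALSE] %*% chol_covs[[k]] +
        matrix(truth$state_means[k, ], sum(at), truth$R, byrow = TRUE)
    }
    paths[[i]] <- path
    data[[i]] <- x
  }
  names(data) <- ids
  region_ids <- sprintf("roi%02d", seq_len(truth$R))
  cohort <- cohort_series(data, tr_seconds = tr_seconds,
                          group_labels = stats::setNames(groups, ids),
                          region_ids = region_ids)
  list(cohort = cohort,
       paths = state_path_set(stats::setNames(paths, ids), K = truth$K))
}

#' Simulate facial action-unit recordings for two groups
#'
#' Each of the 16 emotion-relevant AUs is baseline AR(1) noise plus
#' event-locked gamma-shaped responses at the supplied event frames. The six
#' smile-related AUs (06, 07, 09, 12, 14, 25) take a group-specific response
#' amplitude (`amp[1]` for group A, `amp[2]` for group B; `amp[1] < amp[2]`
#' emulates melancholic blunting of positive affect); the remaining AUs share
#' `amp[2]` across groups. Intensities are floored at zero.
#'
#' @param n_per_group integer pair `(n_A, n_B)`.
#' @param n_frames frames per subject (10 fps; a 20-minute clip is 12000).
#' @param event_times frame indices of positive events (1-based).
#' @param amp numeric pair: smile-AU response amplitude in groups A and B.
#' @param ar1 AR(1) coefficient of the baseline noise, in `[0, 1)`.
#' @param noise_sd innovation SD of the baseline noise.
#' @param baseline mean resting intensity added to every series.
#' @param seed RNG seed.
#' @return an `AuMatrix`: list with `series` (per-subject frames x 16
#'   matrices), `au_ids`, `fps`, `group_labels`, `subject_ids`.
#' @export
simulate_au_cohort <- function(n_per_group, n_frames, event_times,
                               amp = c(0.4, 1), ar1 = 0.6, noise_sd = 0.25,
                               baseline = 0.5, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1),
            all(amp >= 0))
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1) for stationarity")
  if (length(event_times) && (min(event_times) < 1 ||
                              max(event_times) > n_frames))
    stop("event times outside frame range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fps <- 10
  # gamma-shaped response kernel peaking ~1 s after the event, ~4 s long
  kt <- seq(0, 4, by = 1 / fps)
  kernel <- stats::dgamma(kt, shape = 2, scale = 0.6)
  kernel <- kernel / max(kernel)
  event_sig <- rep(0, n_frames)
  event_sig[event_times] <- 1
  event_resp <- stats::convolve(event_sig, rev(kernel), type = "open")
  event_resp <- event_resp[seq_len(n_frames)]
  n <- sum(n_per_group)
  groups <- rep(c("A", "B"), n_per_group)
  ids <- sprintf("face%02d", seq_len(n))
  smile <- AU_ANALYSIS_SET %in% AU_SMILE_SET
  series <- vector("list", n)
  for (i in seq_len(n)) {
    au_amp <- ifelse(smile, amp[[if (groups[i] == "A") 1L else 2L]], amp[[2L]])
    noise <- vapply(seq_len(16L), function(j)
      as.numeric(stats::arima.sim(list(ar = ar1), n_frames,
                                  sd = noise_sd)), numeric(n_frames))
    m <- baseline + noise + outer(event_resp, au_amp)
    m <- pmax(m, 0)
    colnames(m) <- AU_ANALYSIS_SET
    series[[i]] <- m
  }
  names(series) <- ids
  structure(list(series = series, au_ids = AU_ANALYSIS_SET, fps = fps,
                 group_labels = stats::setNames(groups, ids),
                 subject_ids = ids),
            class = "AuMatrix")
}

#' Simulate paired epoch-level brain and facial measures
#'
#' Emulates the brain-behaviour linkage: each subject has a facial
#' expressivity mean drawn from a common distribution and an ROI epoch
#' coefficient generated as `intercept + slope[group] * facial + noise`.
#' Unequal slopes create a group-by-covariate interaction (a blunted
#' group-A slope emulates melancholia).
#'
#' @param n_per_group integer pair `(n_A, n_B)`.
#' @param slopes numeric pair: regression slope in groups A and B.
#' @param noise_sd residual SD (>= 0).
#' @param intercept common intercept.
#' @param facial_mean,facial_sd distribution of the facial covariate.
#' @param seed RNG seed.
#' @return data frame with columns `subject`, `group`, `facial_mean`,
#'   `roi_beta`.
#' @export
simulate_epoch_behaviour <- function(n_per_group, slopes, noise_sd = 0.2,
                                     intercept = 0, facial_mean = 1,
                                     facial_sd = 0.4, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, length(slopes) == 2L, noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- sum(n_per_group)
  groups <- rep(c("A", "B"), n_per_group)
  facial <- stats::rnorm(n, facial_mean, facial_sd)
  beta <- intercept + ifelse(groups == "A", slopes[1L], slopes[2L]) * facial +
    stats::rnorm(n, 0, noise_sd)
  data.frame(subject = sprintf("sub%02d", seq_len(n)), group = groups,
             facial_mean = facial, roi_beta = beta,
             stringsAsFactors = FALSE)
}
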