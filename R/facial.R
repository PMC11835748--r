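#' Assemble an AU matrix from OpenFace readers
#'
#' @param series named list of frames x 16 AU intensity matrices (e.g. the
#'   `intensities` element of [read_openface_csv()] results).
#' @param group_labels named or ordered group labels, one per subject.
#' @param fps frame rate (default 10 frames/s).
#' @return an `AuMatrix`.
#' @export
au_matrix <- function(series, group_labels, fps = 10) {
  stopifnot(is.list(series), length(series) >= 1L)
  ids <- names(series)
  if (is.null(ids)) ids <- sprintf("face%02d", seq_along(series))
  for (m in series) {
    if (!all(colnames(m) == AU_ANALYSIS_SET))
      stop("AU columns must be the 16 analysis AUs in canonical order")
    if ("AU45" %in% colnames(m)) stop("AU45 must be excluded upstream")
  }
  if (!is.null(names(group_labels))) group_labels <- group_labels[ids]
  structure(list(series = stats::setNames(series, ids),
                 au_ids = AU_ANALYSIS_SET, fps = fps,
                 group_labels = stats::setNames(as.character(group_labels),
                                                ids),
                 subject_ids = ids),
            class = "AuMatrix")
}

#' Per-subject mean AU intensity
#'
#' Means are taken over valid (non-missing) frames only; no per-subject
#' normalisation is applied, mirroring OpenFace's `-au_static` semantics in
#' which individual expressivity differences are preserved.
#'
#' @param aus an `AuMatrix`.
#' @return subjects x 16 matrix of mean intensities.
#' @export
au_mean_intensity <- function(aus) {
  out <- t(vapply(aus$subject_ids, function(sid) {
    m <- aus$series[[sid]]
    nvalid <- colSums(!is.na(m))
    if (any(nvalid == 0))
      stop("subject ", sid, " has no valid frames for ",
           aus$au_ids[which(nvalid == 0)[1L]])
    colMeans(m, na.rm = TRUE)
  }, numeric(length(aus$au_ids))))
  dimnames(out) <- list(aus$subject_ids, aus$au_ids)
  out
}

#' Two-sample t statistic from printed summary statistics
#'
#' Pooled-variance unpaired t for groups summarised by mean, SD and n, as
#' printed in clinical characteristic tables; the sign follows
#' `mean1 - mean2`.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Group comparison of AU mean intensities with FDR correction
#'
#' Two-tailed unpaired t-test per action unit (pooled variance by default,
#' Welch optional) with Benjamini-Hochberg adjustment across the 16-AU
#' family.
#'
#' @param means subjects x AU matrix from [au_mean_intensity()].
#' @param labels two-level group labels in subject order.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data frame (class `AuStats`) with `au`, `mean_A`, `mean_B`, `t`,
#'   `p`, `q`; `t` is `NA` for zero-variance AUs.
#' @export
compare_au_groups <- function(means, labels, var_equal = TRUE) {
  means <- as.matrix(means)
  g <- as.factor(labels)
  stopifnot(nlevels(g) == 2L, min(table(g)) >= 2L)
  a <- g == levels(g)[1L]
  res <- lapply(seq_len(ncol(means)), function(j) {
    x <- means[a, j]; y <- means[!a, j]
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(list(t = NA_real_, p = NA_real_))
    ht <- stats::t.test(x, y, var.equal = var_equal)
    list(t = unname(ht$statistic), p = ht$p.value)
  })
  p <- vapply(res, `[[`, 0, "p")
  out <- data.frame(
    au = colnames(means),
    mean_A = colMeans(means[a, , drop = FALSE]),
    mean_B = colMeans(means[!a, , drop = FALSE]),
    t = vapply(res, `[[`, 0, "t"),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("AuStats", "data.frame")
  out
}

#' First principal component of pooled AU time series
#'
#' Pools all subjects' valid frames into one frames x 16 matrix, centres each
#' AU over the pool (group-blind, so downstream group comparisons of scores
#' are not circular), and extracts the principal axis. The sign is fixed so
#' that the mean loading over the six smile-related AUs is positive.
#'
#' @param aus an `AuMatrix`.
#' @return list with `loadings` (length-16 named vector), `explained`
#'   (variance share), `scores` (per-subject numeric score series), and
#'   `mean_score` (per-subject mean score).
#' @export
first_pc <- function(aus) {
  pooled <- do.call(rbind, lapply(aus$series, function(m)
    m[stats::complete.cases(m), , drop = FALSE]))
  if (nrow(pooled) <= ncol(pooled))
    stop("pooled frame count must exceed the number of AUs")
  centre <- colMeans(pooled)
  sv <- svd(sweep(pooled, 2L, centre), nu = 0L, nv = 1L)
  loadings <- sv$v[, 1L]
  if (mean(loadings[aus$au_ids %in% AU_SMILE_SET]) < 0)
    loadings <- -loadings
  names(loadings) <- aus$au_ids
  total_var <- sum(sweep(pooled, 2L, centre)^2)
  explained <- sv$d[1L]^2 / total_var
  if (explained < 1.5 / length(aus$au_ids))
    warning("pooled AU matrix close to isotropic; first axis weakly defined")
  scores <- lapply(aus$series, function(m)
    as.numeric(sweep(m, 2L, centre) %*% loadings))
  list(loadings = loadings, explained = explained, scores = scores,
       mean_score = vapply(scores, mean, 0, na.rm = TRUE))
}

#' Bootstrap confidence band of a group-mean AU curve
#'
#' Resamples subjects with replacement, recomputes the per-frame group mean,
#' and returns the 5th/95th percentile envelope (1000 bootstrap samples by
#' default).
#'
#' @param series list of equal-length numeric vectors or single-AU series,
#'   one per subject of the group.
#' @param n_boot bootstrap samples (default 1000).
#' @param seed RNG seed.
#' @param probs envelope percentiles (default `c(0.05, 0.95)`).
#' @return list with `mean` (observed per-frame mean), `lower`, `upper`.
#' @export
bootstrap_band <- function(series, n_boot = 1000L, seed = 1L,
                           probs = c(0.05, 0.95)) {
  M <- do.call(rbind, lapply(series, as.numeric))
  n <- nrow(M)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- matrix(0, n_boot, ncol(M))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- colMeans(M[idx, , drop = FALSE], na.rm = TRUE)
  }
  qs <- apply(boots, 2L, stats::quantile, probs = probs, names = FALSE,
              na.rm = TRUE)
  list(mean = colMeans(M, na.rm = TRUE), lower = qs[1L, ], upper = qs[2L, ])
}

#' Correlate AU means with a clinical covariate
#'
#' Pearson correlation of each AU's mean intensity with a per-subject
#' covariate (e.g. anxiety severity), BH-adjusted across AUs. Subjects with
#' a missing covariate are dropped pairwise and the retained count reported.
#'
#' @param means subjects x AU matrix.
#' @param covariate numeric vector in subject order (may contain `NA`).
#' @return data frame with `au`, `r`, `p`, `q`, `n_used`.
#' @export
correlate_with_covariate <- function(means, covariate) {
  means <- as.matrix(means)
  stopifnot(length(covariate) == nrow(means))
  keep <- !is.na(covariate)
  if (sum(keep) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(covariate[keep]) == 0) {
    return(data.frame(au = colnames(means), r = NA_real_, p = NA_real_,
                      q = NA_real_, n_used = sum(keep),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(ncol(means)), function(j) {
    ct <- stats::cor.test(means[keep, j], covariate[keep])
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  p <- vapply(res, `[[`, 0, "p")
  data.frame(au = colnames(means), r = vapply(res, `[[`, 0, "r"), p = p,
             q = stats::p.adjust(p, method = "BH"), n_used = sum(keep),
             row.names = NULL, stringsAsFactors = FALSE)
}
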