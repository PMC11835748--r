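#' Epoch boxcar regression coefficients per subject and region
#'
#' Regresses each subject-by-region trace on an intercept plus the binary
#' positive-epoch boxcar (no haemodynamic convolution). The boxcar
#' coefficient algebraically equals the difference between the mean signal
#' inside and outside the epochs.
#'
#' @param cohort a `CohortSeries` (post-trim).
#' @param mask logical per-volume epoch mask with both `TRUE` and `FALSE`
#'   entries.
#' @return subjects x regions matrix of boxcar coefficients (class kept as
#'   plain matrix; design metadata in attributes `mask_n_on` and
#'   `convolved = FALSE`).
#' @export
epoch_boxcar_beta <- function(cohort, mask) {
  stopifnot(length(mask) == n_volumes(cohort))
  if (all(mask) || !any(mask))
    stop("collinear design: epoch mask must contain both on and off volumes")
  x <- as.numeric(mask)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  betas <- t(vapply(cohort$data, function(m)
    as.numeric(crossprod(xc, m)) / denom, numeric(length(cohort$region_ids))))
  dimnames(betas) <- list(cohort$subject_ids, cohort$region_ids)
  attr(betas, "mask_n_on") <- sum(mask)
  attr(betas, "convolved") <- FALSE
  betas
}

#' Across-subject covariation of an epoch coefficient with facial means
#'
#' Simple regression of the ROI epoch coefficient on the facial expressivity
#' mean across subjects.
#'
#' @param betas numeric vector: one region's epoch coefficients per subject.
#' @param facial numeric vector of per-subject facial means (same order).
#' @return list with `slope`, `intercept`, `r`, `t`, `p`, `n`.
#' @export
group_covariation <- function(betas, facial) {
  keep <- stats::complete.cases(betas, facial)
  if (sum(keep) < 3L) stop("need at least 3 complete pairs")
  x <- facial[keep]; y <- betas[keep]
  if (stats::sd(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                t = NA_real_, p = NA_real_, n = sum(keep)))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = unname(sign(stats::coef(fit)[2L]) * sqrt(s$r.squared)),
       t = unname(s$coefficients[2L, "t value"]),
       p = unname(s$coefficients[2L, "Pr(>|t|)"]),
       n = sum(keep))
}

#' ANCOVA group-by-covariate interaction on epoch coefficients
#'
#' Fits `beta ~ group + facial + group:facial` and tests the interaction by
#' the extra-sum-of-squares F against the parallel-slopes model (1 and n - 4
#' degrees of freedom), the analysis-of-covariance separate-lines test.
#' Points beyond 2.5 SD of their group mean (on either variable) are
#' reported, not removed.
#'
#' @param betas numeric vector of epoch coefficients per subject.
#' @param facial numeric vector of facial means per subject.
#' @param labels two-level group labels per subject.
#' @return an `InteractionResult` list: per-group `slopes` and `intercepts`,
#'   `F`, `df`, `p`, `n_per_group`, `outliers` (subject indices beyond 2.5
#'   SD).
#' @export
ancova_interaction <- function(betas, facial, labels) {
  g <- as.factor(labels)
  stopifnot(nlevels(g) == 2L)
  keep <- stats::complete.cases(betas, facial, g)
  betas <- betas[keep]; facial <- facial[keep]; g <- droplevels(g[keep])
  if (min(table(g)) < 3L) stop("need at least 3 complete pairs per group")
  if (stats::sd(facial) == 0) stop("rank-deficient design: constant covariate")
  full <- stats::lm(betas ~ g * facial)
  if (any(is.na(stats::coef(full)))) stop("rank-deficient interaction design")
  reduced <- stats::lm(betas ~ g + facial)
  an <- stats::anova(reduced, full)
  Fval <- an$F[2L]; pval <- an$`Pr(>F)`[2L]
  cf <- stats::coef(full)
  lev <- levels(g)
  slopes <- c(cf[["facial"]], cf[["facial"]] + cf[[4L]])
  intercepts <- c(cf[[1L]], cf[[1L]] + cf[[2L]])
  names(slopes) <- names(intercepts) <- lev
  out_flag <- unlist(lapply(lev, function(l) {
    at <- which(g == l)
    z1 <- abs(scale(betas[at])); z2 <- abs(scale(facial[at]))
    at[z1 > 2.5 | z2 > 2.5]
  }))
  structure(list(slopes = slopes, intercepts = intercepts,
                 F = Fval, df = unname(c(1L, an$Res.Df[2L])), p = pval,
                 n_per_group = as.integer(table(g)),
                 outliers = as.integer(out_flag)),
            class = "InteractionResult")
}

#' @export
print.InteractionResult <- function(x, ...) {
  cat(sprintf("ANCOVA interaction: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  cat(sprintf("  slopes: %s = %.3f, %s = %.3f (n = %d, %d)\n",
              names(x$slopes)[1L], x$slopes[1L], names(x$slopes)[2L],
              x$slopes[2L], x$n_per_group[1L], x$n_per_group[2L]))
  if (length(x$outliers))
    cat("  points beyond 2.5 SD (reported, not removed):",
        paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
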