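#' Non-overlapping patch means of a 2D map
#'
#' Means over `patch` x `patch` pixel blocks in row-major order; trailing
#' partial patches are dropped. Mirrors the patch-wise comparison of
#' histology-derived and model-derived density maps.
#'
#' @param map2d numeric matrix (dimensions >= patch).
#' @param patch patch edge in pixels (default 5).
#' @return numeric vector of patch means.
#' @export
patch_aggregate <- function(map2d, patch = 5L) {
  patch <- as.integer(patch)
  if (patch < 1L) stop("patch must be >= 1", call. = FALSE)
  if (nrow(map2d) < patch || ncol(map2d) < patch)
    stop("map smaller than patch", call. = FALSE)
  nr <- nrow(map2d) %/% patch
  nc <- ncol(map2d) %/% patch
  out <- numeric(nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {        # row-major: sweep columns within a row
    for (j in seq_len(nc)) {
      k <- k + 1L
      out[k] <- mean(map2d[((i - 1L) * patch + 1L):(i * patch),
                           ((j - 1L) * patch + 1L):(j * patch)])
    }
  }
  out
}

#' Ordinary least-squares regression with a 95% confidence band
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @param ci_x x positions for the pointwise 95% confidence band of the
#'   mean (default: sorted unique x).
#' @return object of class `regression_result`: slope, intercept,
#'   r_squared (squared Pearson correlation), p_value (two-sided, slope
#'   != 0), ci95 (data.frame x, fit, lo, hi), n.
#' @export
linear_regression <- function(x, y, ci_x = NULL) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  if (is.null(ci_x)) ci_x <- sort(unique(x))
  pr <- stats::predict(fit, newdata = data.frame(x = ci_x),
                       interval = "confidence", level = 0.95)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = unname(stats::cor(x, y)^2),
    p_value = unname(sm$coefficients[2, 4]),
    ci95 = data.frame(x = ci_x, fit = pr[, "fit"], lo = pr[, "lwr"],
                      hi = pr[, "upr"]),
    n = length(x)), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "regression_result: slope %.4f, intercept %.4f, r^2 %.4f, p %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by full enumeration of the rank-sum distribution over
#' all group assignments when the combined sample size is <= 12 (ties
#' handled by enumerating the actual, possibly tied, ranks); normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @return list(statistic = rank sum of group_a, p_value, method).
#' @export
ranksum_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  r <- rank(c(group_a, group_b))
  W <- sum(r[seq_len(na)])
  N <- na + nb
  if (N <= 12L) {
    sums <- apply(utils::combn(N, na), 2, function(ix) sum(r[ix]))
    p <- 2 * min(mean(sums <= W), mean(sums >= W))
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) return(list(statistic = W, p_value = 1,
                               method = "degenerate (all tied)"))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)  # continuity corrected
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, method = method)
}

#' Regression of estimated cellularity on true density at one SNR
#'
#' @param table a region density table: data.frame with columns
#'   region_id, true_density, estimated_cellularity, snr.
#' @param snr the stratum to regress (must have >= 10 regions).
#' @return a `regression_result` with an extra `slope_distance_from_1`
#'   element.
#' @export
validation_regression <- function(table, snr) {
  sub <- table[table$snr == snr, ]
  if (nrow(sub) == 0) stop("no rows at snr = ", snr, call. = FALSE)
  if (nrow(sub) < 10L) stop("need >= 10 regions in the stratum",
                            call. = FALSE)
  res <- linear_regression(sub$true_density, sub$estimated_cellularity)
  res$slope_distance_from_1 <- abs(res$slope - 1)
  res
}

#' Longitudinal per-group trends and per-visit group comparisons
#'
#' Per group: OLS regression of patient-mean cellularity on gestational
#' week. Per visit: two-sided Wilcoxon rank-sum comparison between the
#' groups, reported uncorrected (matching the per-visit presentation) with
#' a Bonferroni column for transparency.
#'
#' @param cohort_table data.frame (patient_id, group, visit_week,
#'   mean_cellularity) as from [generate_cohort()].
#' @return list with `regressions` (named list of `regression_result` per
#'   group, NULL with a warning if only one visit) and `comparisons`
#'   (data.frame visit_week, n per group, group means, W, p_value,
#'   p_bonferroni).
#' @export
longitudinal_summary <- function(cohort_table) {
  stopifnot(all(c("group", "visit_week", "mean_cellularity") %in%
                  names(cohort_table)))
  groups <- unique(cohort_table$group)
  visits <- sort(unique(cohort_table$visit_week))
  regressions <- NULL
  if (length(visits) >= 2L) {
    regressions <- lapply(stats::setNames(groups, groups), function(g) {
      sub <- cohort_table[cohort_table$group == g, ]
      linear_regression(sub$visit_week, sub$mean_cellularity)
    })
  } else {
    warning("single-visit input: longitudinal regression skipped")
  }
  comparisons <- NULL
  if (length(groups) == 2L) {
    comparisons <- do.call(rbind, lapply(visits, function(v) {
      a <- cohort_table$mean_cellularity[
        cohort_table$group == groups[1] & cohort_table$visit_week == v]
      b <- cohort_table$mean_cellularity[
        cohort_table$group == groups[2] & cohort_table$visit_week == v]
      if (length(a) < 2L || length(b) < 2L)
        stop("need >= 2 patients per group per visit", call. = FALSE)
      ts <- ranksum_test(a, b)
      data.frame(visit_week = v,
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b),
                 W = ts$statistic, p_value = ts$p_value,
                 p_bonferroni = min(1, ts$p_value * length(visits)))
    }))
  }
  list(regressions = regressions, comparisons = comparisons,
       groups = groups)
}

#' Two-sample t-test on a cohort covariate (demographics-style utility)
#' @param a,b numeric vectors.
#' @return p-value of a Welch two-sample t-test.
#' @export
covariate_ttest <- function(a, b) stats::t.test(a, b)$p.value
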