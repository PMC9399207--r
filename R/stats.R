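#' ROC analysis with Youden-maximized cut-off
#'
#' Empirical ROC over all thresholds (taken midway between consecutive
#' distinct scores), trapezoidal AUC with ties counted one half, and the
#' cut-off maximizing Youden's J = sensitivity + specificity - 1. When
#' several thresholds attain the maximal J, the one most conservative for
#' positivity (the largest) is reported and all maximizers are listed.
#'
#' @param scores Numeric scores.
#' @param truth_positive Logical ground truth (both classes present).
#' @param positive_direction `"higher"` if positives have higher scores
#'   (e.g. Centiloids), `"lower"` if lower scores indicate positivity
#'   (e.g. distance to the hyperplane).
#' @return An object of class `roc_result`: `auc` (fraction in `[0, 1]`),
#'   `best_threshold`, `specificity` and `sensitivity` at that threshold
#'   (percent), `all_best_thresholds`, and the full `curve` data.frame
#'   (threshold, sensitivity, specificity).
#' @export
roc_youden <- function(scores, truth_positive,
                       positive_direction = c("higher", "lower")) {
  positive_direction <- match.arg(positive_direction)
  scores <- as.numeric(scores)
  truth <- as.logical(truth_positive)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth)) {
    stop("scores and truth must be complete and the same length")
  }
  if (!any(truth) || all(truth)) stop("both classes must be present")
  direction <- if (positive_direction == "higher") "<" else ">"
  r <- pROC::roc(response = truth, predictor = scores, direction = direction,
                 levels = c(FALSE, TRUE), quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      sensitivity = 100 * r$sensitivities,
                      specificity = 100 * r$specificities)
  j <- r$sensitivities + r$specificities - 1
  best <- which(j >= max(j) - 1e-12)
  cand <- curve$threshold[best]
  pick <- if (any(is.finite(cand))) max(cand[is.finite(cand)]) else max(cand)
  at <- best[which(cand == pick)[1]]
  structure(
    list(auc = as.numeric(r$auc), best_threshold = pick,
         specificity = curve$specificity[at], sensitivity = curve$sensitivity[at],
         youden = j[at], all_best_thresholds = sort(cand), curve = curve,
         positive_direction = positive_direction),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.1f%%, Youden cut-off = %.4g (spec %.1f%%, sens %.1f%%)\n",
    100 * x$auc, x$best_threshold, x$specificity, x$sensitivity))
  invisible(x)
}

#' Pearson and Spearman association of two variables
#'
#' @param x,y Numeric vectors of common length `n >= 3` with positive
#'   variance.
#' @return List with `pearson_r`, `slope` (OLS slope of y on x),
#'   `spearman_rho`, `spearman_p`, and `n`.
#' @export
correlations <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3 || anyNA(x) || anyNA(y)) {
    stop("x and y must be complete, equal-length, n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = stats::cor(x, y),
       slope = stats::cov(x, y) / stats::var(x),
       spearman_rho = as.numeric(ct$estimate),
       spearman_p = ct$p.value,
       n = length(x))
}

#' Compare two overlapping correlations on dependent groups
#'
#' Tests whether `cor(x, y1)` differs from `cor(x, y2)` when all three
#' variables are measured on the same subjects, using Dunn & Clark's z on
#' Fisher-transformed correlations, the canonical test for two overlapping
#' correlations sharing the variable `x`.
#'
#' @param x,y1,y2 Numeric vectors of common length `n >= 4`.
#' @return An object of class `correlation_comparison`: `r12 = cor(x, y1)`,
#'   `r13 = cor(x, y2)`, `r23 = cor(y1, y2)`, `n`, the `z` statistic, the
#'   two-sided normal `p`, and a `method` tag.
#' @export
compare_overlapping_correlations <- function(x, y1, y2) {
  x <- as.numeric(x); y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(x)
  if (length(y1) != n || length(y2) != n || n < 4 ||
      anyNA(x) || anyNA(y1) || anyNA(y2)) {
    stop("x, y1, y2 must be complete, equal-length, n >= 4")
  }
  r12 <- stats::cor(x, y1); r13 <- stats::cor(x, y2); r23 <- stats::cor(y1, y2)
  if (any(abs(c(r12, r13)) >= 1)) {
    stop("perfect correlation: the Fisher z transform is undefined")
  }
  z12 <- atanh(r12); z13 <- atanh(r13)
  if (z12 == z13) {
    # equal correlations (e.g. y1 identical to y2): the statistic is 0 by
    # definition, even where the variance expression degenerates (r23 = 1)
    return(structure(
      list(r12 = r12, r13 = r13, r23 = r23, n = n, z = 0, p = 1,
           method = "dunn_clark_1969"),
      class = "correlation_comparison"))
  }
  cov_term <- (r23 * (1 - r12^2 - r13^2) -
                 0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)) /
    ((1 - r12^2) * (1 - r13^2))
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_term))
  structure(
    list(r12 = r12, r13 = r13, r23 = r23, n = n, z = z,
         p = 2 * stats::pnorm(-abs(z)), method = "dunn_clark_1969"),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "<correlation_comparison> r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d): z = %.3f, p = %.3g\n",
    x$r12, x$r13, x$r23, x$n, x$z, x$p))
  invisible(x)
}

check_groups <- function(groups, min_n = 2, need_variance = TRUE) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, anyNA, logical(1)))) stop("groups must be complete")
  if (any(vapply(groups, length, integer(1)) < min_n)) {
    stop("each group needs at least ", min_n, " observations")
  }
  if (need_variance && any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("zero-variance group")
  }
  groups
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   observations and positive variance).
#' @return List with `statistic` (Welch's F*), `df1`, `df2`
#'   (Welch-Satterthwaite denominator df) and `p`.
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(statistic = as.numeric(fit$statistic),
       df1 = as.numeric(fit$parameter[1]),
       df2 = as.numeric(fit$parameter[2]),
       p = fit$p.value)
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' All pairwise two-sided Welch t-tests between groups; p-values are
#' adjusted as `min(1, m * p)` with `m` the number of pairs.
#'
#' @inheritParams welch_anova
#' @return List with `p_raw` and `p_adjusted`: symmetric matrices with one
#'   row/column per group.
#' @export
pairwise_welch_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  nm <- if (!is.null(names(groups))) names(groups) else as.character(seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- stats::t.test(groups[[i]], groups[[j]], var.equal = FALSE)$p.value
      p[i, j] <- p[j, i] <- pv
    }
  }
  m <- k * (k - 1) / 2
  list(p_raw = p, p_adjusted = pmin(m * p, 1), n_pairs = m)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected Kruskal-Wallis H. The fully degenerate case (all pooled
#' values identical) returns `H = 0, p = 1` rather than an error.
#'
#' @param groups List of >= 2 numeric vectors, each non-empty.
#' @return List with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups, min_n = 1, need_variance = FALSE)
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::kruskal.test(values, g)
  list(statistic = as.numeric(fit$statistic),
       df = as.numeric(fit$parameter), p = fit$p.value)
}

# exact two-sided permutation p for the Mann-Whitney U by enumerating all
# group assignments (used when both groups have <= `exact_max` cases)
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  mu <- n1 * length(y) / 2
  u_obs <- mw_u(x, y)
  u_all <- apply(combs, 2, function(idx) mw_u(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Mann-Whitney U for x: pairs with x > y count 1, ties count 1/2
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both groups of size at most
#' `exact_max`) the p-value comes from exhaustive enumeration of all group
#' assignments (handling ties exactly); above that, the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Enumeration size bound per group (default 8).
#' @return List with `u` (U statistic of `x`, ties counted one half),
#'   `p`, and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y)) {
    stop("both samples must be non-empty and complete")
  }
  u <- mw_u(x, y)
  if (length(x) <= exact_max && length(y) <= exact_max) {
    list(u = u, p = mw_exact_p(x, y), method = "exact_enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(u = u, p = wt$p.value, method = "normal_approximation")
  }
}
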