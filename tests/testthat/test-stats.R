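test_that("ROC handles separation, ties, and direction", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_gt(r$best_threshold, 3); expect_lt(r$best_threshold, 10)
  const <- roc_youden(rep(1, 10), rep(c(F, T), 5))
  expect_equal(const$auc, 0.5)
  # lower-is-positive direction mirrors the distance convention
  rl <- roc_youden(c(-3, -2, -1, 5, 6, 7), c(T, T, T, F, F, F),
                   positive_direction = "lower")
  expect_equal(rl$auc, 1)
  expect_error(roc_youden(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid AUC equals the pairwise count oracle on random data", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- roc_youden(scores, truth)
    expect_equal(r$auc, oracle_auc_count(scores, truth), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(22)
  scores <- rnorm(40); truth <- scores + rnorm(40) > 0
  a <- roc_youden(scores, truth)
  b <- roc_youden(exp(scores), truth)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  # complementarity for tie-free scores
  c1 <- roc_youden(scores, truth)
  c2 <- roc_youden(-scores, truth)
  expect_equal(c1$auc + c2$auc, 1, tolerance = 1e-12)
})

test_that("correlations match their definitional oracles", {
  x <- seq(-3, 3, length.out = 20)
  r <- correlations(x, 2 * x)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 2)
  r2 <- correlations(x, -x^3)
  expect_equal(r2$spearman_rho, -1)
  set.seed(23)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  r3 <- correlations(a, b)
  expect_equal(r3$pearson_r, sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_equal(r3$slope, oracle_ols(a, b)$slope)
  expect_equal(r3$spearman_rho, cor(rank(a), rank(b)))
  expect_error(correlations(rep(1, 5), 1:5), "zero variance")
})

test_that("identical predictors give a null overlapping-correlation comparison", {
  set.seed(24)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  cmp <- compare_overlapping_correlations(x, y, y)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  # swapping the predictors negates z and preserves p
  y2 <- 0.2 * x + rnorm(30)
  a <- compare_overlapping_correlations(x, y, y2)
  b <- compare_overlapping_correlations(x, y2, y)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_overlapping_correlations(x, x, y), "perfect correlation")
})

test_that("clearly different dependent correlations are detected", {
  set.seed(25)
  n <- 500
  x <- rnorm(n)
  y1 <- 0.9 * x + rnorm(n, 0, sqrt(1 - 0.81))
  y2 <- 0.1 * x + rnorm(n, 0, sqrt(1 - 0.01))
  cmp <- compare_overlapping_correlations(x, y1, y2)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$z, 0)
})

test_that("the dependent-correlation p agrees with a bootstrap oracle mid-range", {
  set.seed(26)
  n <- 50
  x <- rnorm(n)
  y1 <- 0.55 * x + rnorm(n, 0, 1)
  y2 <- 0.35 * x + rnorm(n, 0, 1)
  cmp <- compare_overlapping_correlations(x, y1, y2)
  boots <- replicate(4000, {
    idx <- sample(n, replace = TRUE)
    atanh(cor(x[idx], y1[idx])) - atanh(cor(x[idx], y2[idx]))
  })
  p_boot <- 2 * pnorm(-abs(atanh(cmp$r12) - atanh(cmp$r13)) / sd(boots))
  expect_lt(abs(cmp$p - p_boot), 0.06)
})

test_that("Welch's F on two groups is the squared Welch t", {
  set.seed(27)
  g <- list(rnorm(12, 0, 1), rnorm(20, 0.8, 2.5))
  w <- welch_anova(g)
  t2 <- t.test(g[[1]], g[[2]], var.equal = FALSE)
  expect_equal(w$statistic, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(w$df2, unname(t2$parameter), tolerance = 1e-10)
  expect_equal(w$p, t2$p.value, tolerance = 1e-10)
  expect_error(welch_anova(list(rep(1, 5), rnorm(5))), "zero-variance")
})

test_that("Welch's F matches the hand-computed formula on three small groups", {
  g <- list(c(1.1, 2.3, 0.8, 1.9), c(3.2, 4.1, 2.8, 3.9, 3.3), c(0.5, 1.5, 1.0))
  w <- welch_anova(g)
  o <- oracle_welch_f(g)
  expect_equal(w$statistic, o$f, tolerance = 1e-10)
  expect_equal(w$df1, o$df1)
  expect_equal(w$df2, o$df2, tolerance = 1e-10)
})

test_that("Welch's ANOVA holds its nominal size under the null", {
  set.seed(28)
  rejections <- mean(replicate(2000, {
    welch_anova(list(rnorm(8), rnorm(8, 0, 3), rnorm(12)))$p < 0.05
  }))
  expect_lt(abs(rejections - 0.05), 0.015)
})

test_that("pairwise Welch tests apply the multiplication rule", {
  set.seed(29)
  g <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  pw <- pairwise_welch_bonferroni(g)
  expect_equal(pw$n_pairs, 3)
  expect_equal(pw$p_adjusted, pmin(3 * pw$p_raw, 1))
  # identically distributed pair (same values, reordered): t = 0, p = 1
  same <- pairwise_welch_bonferroni(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(same$p_adjusted[1, 2], 1)
  # fuzzed monotonicity: adjusted >= raw and <= 1
  for (i in 1:20) {
    k <- sample(2:5, 1)
    gg <- lapply(seq_len(k), function(j) rnorm(sample(3:10, 1), mean = rnorm(1)))
    pwf <- pairwise_welch_bonferroni(gg)
    off <- upper.tri(pwf$p_raw)
    expect_true(all(pwf$p_adjusted[off] >= pwf$p_raw[off]))
    expect_true(all(pwf$p_adjusted[off] <= 1))
  }
})

test_that("rank tests match enumeration and handle degeneracy", {
  expect_equal(mann_whitney(c(5, 6, 7), c(1, 2, 3, 4))$u, 12)  # n1 * n2
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  deg <- kruskal_wallis(list(rep(2, 4), rep(2, 3)))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p, 1)
  set.seed(30)
  for (i in 1:10) {
    x <- if (i %% 2) rnorm(sample(3:6, 1)) else sample(1:4, sample(3:6, 1), TRUE)
    y <- if (i %% 2) rnorm(sample(3:6, 1)) else sample(2:5, sample(3:6, 1), TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$method, "exact_enumeration")
    expect_equal(mw$p, oracle_mw_p(x, y), tolerance = 1e-12)
  }
  # tie-free exact enumeration agrees with the classical exact distribution
  set.seed(31)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  xa <- rnorm(30); ya <- rnorm(25, 0.5)
  big <- mann_whitney(xa, ya)
  expect_equal(big$method, "normal_approximation")
  expect_equal(big$p,
               suppressWarnings(wilcox.test(xa, ya, exact = FALSE,
                                            correct = TRUE))$p.value)
})

test_that("Kruskal-Wallis agrees with base R's tie-corrected statistic", {
  set.seed(32)
  g <- list(sample(1:5, 8, TRUE), sample(2:6, 6, TRUE), sample(1:6, 7, TRUE))
  kw <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), factor(rep(1:3, lengths(g))))
  expect_equal(kw$statistic, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
})
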