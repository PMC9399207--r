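# Independent oracles used across the suite. These deliberately use naive,
# transparent algorithms (dense loops, exhaustive enumeration) so they stay
# independent of the implementation paths they check.

# dense separable Gaussian convolution with mirror-reflection padding,
# written as an explicit triple loop over output voxels
oracle_smooth3d <- function(values, spacing, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(ax) {
    s <- sigma / spacing[ax]
    r <- max(1L, ceiling(6 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  reflect <- function(i, n) {
    # mirror including the edge sample: 0 -> 1, -1 -> 2, n+1 -> n
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  d <- dim(values)
  out <- array(0, d)
  rs <- vapply(kernels, function(k) (length(k) - 1L) / 2L, numeric(1))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (i in -rs[1]:rs[1]) for (j in -rs[2]:rs[2]) for (l in -rs[3]:rs[3]) {
      acc <- acc + kernels[[1]][i + rs[1] + 1] * kernels[[2]][j + rs[2] + 1] *
        kernels[[3]][l + rs[3] + 1] *
        values[reflect(x + i, d[1]), reflect(y + j, d[2]), reflect(z + l, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# Exhaustive KKT oracle for the C-SVM dual: enumerate every assignment of
# cases to {alpha = 0, alpha = C, free}, solve the stationarity system for
# the free block, and keep the assignment whose solution satisfies all KKT
# conditions. Tractable for n <= 8. y in {-1, +1}; returns w and b.
oracle_svm_qp <- function(X, y, C = 1, tol = 1e-9) {
  n <- length(y)
  K <- tcrossprod(X)
  Q <- (y %o% y) * K
  best <- NULL
  states <- expand.grid(rep(list(0:2), n))  # 0: lower, 1: upper, 2: free
  for (row in seq_len(nrow(states))) {
    st <- as.integer(states[row, ])
    low <- which(st == 0); up <- which(st == 1); fr <- which(st == 2)
    alpha <- numeric(n); alpha[up] <- C
    if (length(fr)) {
      # stationarity on free block: Q_ff a_f + Q_fu C + lambda y_f = 1
      A <- rbind(cbind(Q[fr, fr, drop = FALSE], y[fr]), c(y[fr], 0))
      qterm <- if (length(up))
        as.numeric(Q[fr, up, drop = FALSE] %*% rep(C, length(up)))
      else rep(0, length(fr))
      rhs <- c(rep(1, length(fr)) - qterm, -sum(C * y[up]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[fr] <- sol[seq_along(fr)]
      lambda <- sol[length(sol)]
      if (any(alpha[fr] < -tol) || any(alpha[fr] > C + tol)) next
    } else {
      if (abs(sum(alpha * y)) > tol) next
      # no free block: lambda (= b) ranges over the interval where all
      # bound multipliers keep the right sign; take the midpoint, matching
      # the implementation's midpoint convention for the bias
      grad <- as.numeric(Q %*% alpha) - 1
      lo_set <- c(-grad[low][y[low] > 0], grad[up][y[up] < 0])
      hi_set <- c(grad[low][y[low] < 0], -grad[up][y[up] > 0])
      lo <- if (length(lo_set)) max(lo_set) else -Inf
      hi <- if (length(hi_set)) min(hi_set) else Inf
      if (lo > hi + tol) next
      lambda <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
        else if (is.finite(lo)) lo else hi
    }
    grad <- as.numeric(Q %*% alpha) - 1
    mu <- grad + lambda * y
    if (any(mu[low] < -tol) || any(mu[up] > tol)) next
    if (length(fr) && any(abs(mu[fr]) > 1e-6)) next
    obj <- 0.5 * sum(alpha * (Q %*% alpha)) - sum(alpha)
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(alpha = alpha, b = lambda, obj = obj)
    }
  }
  stopifnot(!is.null(best))
  list(w = as.numeric(crossprod(X, best$alpha * y)), b = best$b,
       alpha = best$alpha)
}

# AUC as the scaled Mann-Whitney count: pairs where the positive scores
# higher count 1, ties count one half
oracle_auc_count <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# exact two-sided Mann-Whitney p by enumerating group assignments with
# explicit pair counting (independent of the package's rank-based U)
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  u_of <- function(a, b) {
    tot <- 0
    for (i in a) for (j in b) tot <- tot + (i > j) + 0.5 * (i == j)
    tot
  }
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  hits <- 0
  for (cc in seq_len(ncol(combs))) {
    u <- u_of(pooled[combs[, cc]], pooled[-combs[, cc]])
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# ordinary least squares through the normal equations
oracle_ols <- function(x, y) {
  sx <- sum(x); sxx <- sum(x^2); sy <- sum(y); sxy <- sum(x * y); n <- length(x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

# hand-written Welch heteroscedastic F for k groups
oracle_welch_f <- function(groups) {
  k <- length(groups)
  n <- lengths(groups); m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  den <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - w / sum(w))^2 / (n - 1))
  f <- num / den
  df2 <- (k^2 - 1) / (3 * sum((1 - w / sum(w))^2 / (n - 1)))
  list(f = f, df1 = k - 1, df2 = df2)
}
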