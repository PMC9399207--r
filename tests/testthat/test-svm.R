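test_that("the symmetric two-point problem gives the midpoint hyperplane", {
  X <- matrix(c(-1, 1), ncol = 1)
  clf <- fit_linear_svm(X, positive = c(FALSE, TRUE))
  # pathological case at +1 must sit on the negative side at distance 1
  expect_equal(distance_to_hyperplane(clf, 1), -1)
  expect_equal(distance_to_hyperplane(clf, -1), +1)
  expect_equal(distance_to_hyperplane(clf, 0), 0)
  expect_equal(classify(clf, 1), "positive")
  expect_equal(classify(clf, -1), "negative")
  expect_equal(classify(clf, 0), "negative")  # on-plane tie rule
})

test_that("separable blobs are classified with zero training error", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, mean = 0), 10, 2),
             matrix(rnorm(20, mean = 4), 10, 2))
  pos <- rep(c(FALSE, TRUE), each = 10)
  clf <- fit_linear_svm(X, pos)
  d <- apply(X, 1, function(x) distance_to_hyperplane(clf, x))
  expect_true(all(d[pos] < 0))
  expect_true(all(d[!pos] > 0))
  expect_error(fit_linear_svm(X, rep(TRUE, 20)), "both classes")
})

test_that("the fitted hyperplane matches the exhaustive KKT enumeration oracle", {
  set.seed(100)
  for (case in 1:25) {
    n <- sample(4:8, 1); p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    pos <- seq_len(n) > n / 2
    X[pos, 1] <- X[pos, 1] + runif(1, 1, 3)
    clf <- fit_linear_svm(X, pos)
    o <- oracle_svm_qp(X, ifelse(pos, -1, 1))
    expect_lt(sqrt(sum((clf$weights - o$w)^2)) / sqrt(sum(o$w^2)), 1e-6)
    expect_equal(clf$bias, o$b, tolerance = 1e-6)
  }
})

test_that("the fitted hyperplane agrees with an independent libsvm fit", {
  set.seed(200)
  for (case in 1:10) {
    n <- sample(10:30, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    pos <- seq_len(n) > n / 2
    X[pos, ] <- X[pos, ] + 1
    clf <- fit_linear_svm(X, pos)
    m <- e1071::svm(X, factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos")),
                    kernel = "linear", cost = 1, scale = FALSE,
                    tolerance = 1e-10)
    w_ref <- drop(t(m$coefs) %*% m$SV)
    d_ours <- apply(X, 1, function(x) sum(clf$weights * x) + clf$bias)
    # libsvm's label orientation is its own; compare decision values up to
    # the overall sign
    d_ref <- drop(X %*% w_ref) - m$rho
    s <- sign(stats::cor(d_ours, d_ref))
    expect_equal(d_ours, s * d_ref, tolerance = 1e-5)
  }
})

test_that("scaling the features rescales the hyperplane but not the decisions", {
  # in the zero-slack regime the solution is the hard-margin one, which is
  # exactly scale-equivariant: w -> w / c, decisions and orderings fixed
  set.seed(5)
  X <- matrix(rnorm(40, sd = 0.5), 20, 2); pos <- seq_len(20) > 10
  X[pos, ] <- X[pos, ] + 4
  clf1 <- fit_linear_svm(X, pos)
  clf2 <- fit_linear_svm(3 * X, pos)
  expect_equal(clf2$weights, clf1$weights / 3, tolerance = 1e-8)
  d1 <- apply(X, 1, function(x) distance_to_hyperplane(clf1, x))
  d2 <- apply(3 * X, 1, function(x) distance_to_hyperplane(clf2, x))
  expect_identical(d1 < 0, d2 < 0)
  expect_identical(order(d1), order(d2))
  expect_equal(d2, 3 * d1, tolerance = 1e-8)
})

test_that("geometric distance and classification follow their definitions", {
  clf <- linear_classifier(c(3, 4), 0)
  expect_equal(distance_to_hyperplane(clf, c(3, 4)), 5)
  expect_equal(distance_to_hyperplane(clf, c(0, 0)), 0)
  clfb <- linear_classifier(c(3, 4), -5)
  expect_equal(distance_to_hyperplane(clfb, c(3, 4)), 4)
  expect_error(linear_classifier(c(0, 0), 1), "positive norm")
  expect_error(distance_to_hyperplane(clf, c(1, 2, 3)), "feature mask")
})

test_that("confusion metrics reproduce hand-computed rates", {
  all_ok <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(unlist(all_ok), c(specificity = 100, sensitivity = 100,
                                 accuracy = 100))
  # 29 negatives with 3 false positives, 72 positives with 10 false negatives
  truth <- rep(c(FALSE, TRUE), c(29, 72))
  pred <- truth
  pred[1:3] <- TRUE          # 3 FP
  pred[30:39] <- FALSE       # 10 FN
  m <- confusion_metrics(pred, truth)
  expect_equal(m$specificity, 100 * 26 / 29, tolerance = 1e-12)
  expect_equal(m$sensitivity, 100 * 62 / 72, tolerance = 1e-12)
  expect_equal(round(m$specificity, 1), 89.7)
  expect_equal(round(m$sensitivity, 1), 86.1)
  inv <- confusion_metrics(!truth[1:58], truth[1:58])
  expect_equal(inv$accuracy, 0)
  # one-class truth: the undefined rate is NA, not NaN
  one <- confusion_metrics(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(one$specificity))
  expect_equal(one$sensitivity, 50)
})

test_that("the mean classifier is the componentwise average", {
  set.seed(6)
  clfs <- lapply(1:50, function(i) linear_classifier(rnorm(7), rnorm(1)))
  avg <- mean_classifier(clfs)
  w_sum <- rep(0, 7); b_sum <- 0
  for (cl in clfs) { w_sum <- w_sum + cl$weights; b_sum <- b_sum + cl$bias }
  expect_equal(avg$weights, w_sum / 50)
  expect_equal(avg$bias, b_sum / 50)
  same <- mean_classifier(list(clfs[[1]], clfs[[1]]))
  expect_equal(same$weights, clfs[[1]]$weights)
  # exact cancellation violates the positive-norm invariant
  pair <- list(linear_classifier(c(1, -2), 3), linear_classifier(c(-1, 2), -3))
  expect_error(mean_classifier(pair), "positive norm")
  # inconsistent masks are rejected
  m1 <- array(c(TRUE, FALSE), c(2, 1, 1)); m2 <- array(c(FALSE, TRUE), c(2, 1, 1))
  expect_error(mean_classifier(list(linear_classifier(1, 0, m1),
                                    linear_classifier(1, 0, m2))),
               "inconsistent")
})

test_that("top-weight selection keeps round(fraction * n) voxels with index tie-break", {
  w <- c(0.1, -5, 0.3, 2, -0.2, 0.05, 1, -1, 0.4, 0.15)
  clf <- linear_classifier(w, 0)
  sel <- top_fraction_mask(clf, 0.1)
  expect_equal(which(sel), 2)  # single max |w|
  expect_identical(top_fraction_mask(clf, 1.0), rep(TRUE, 10))
  tied <- linear_classifier(rep(2, 100), 0)
  expect_equal(which(top_fraction_mask(tied, 0.1)), 1:10)
  expect_equal(sum(top_fraction_mask(linear_classifier(rnorm(37), 0), 0.25)),
               round(0.25 * 37))
  expect_error(top_fraction_mask(clf, 0), "\\(0, 1\\]")
  expect_error(top_fraction_mask(clf, 1.2), "\\(0, 1\\]")
  # volume mapping places selected voxels at the mask's linear indices
  mask <- array(FALSE, c(2, 2, 2)); mask[c(1, 3, 6, 8)] <- TRUE
  clfv <- linear_classifier(c(0.1, 9, 0.2, 3), 0, mask)
  vol <- top_fraction_mask(clfv, 0.5)
  expect_equal(which(vol), c(3, 8))
})

test_that("classifier serialization round-trips through NIfTI + JSON", {
  mask <- array(FALSE, c(6, 6, 6)); mask[sample(216, 40)] <- TRUE
  w <- rnorm(40); w[w == 0] <- 0.1
  clf <- linear_classifier(w, 1.25, mask)
  path <- tempfile(fileext = ".nii.gz")
  write_classifier(clf, path)
  back <- read_classifier(path)
  expect_equal(back$weights, clf$weights, tolerance = 1e-6)
  expect_equal(back$bias, clf$bias)
  expect_equal(which(back$feature_mask), which(clf$feature_mask))
})
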