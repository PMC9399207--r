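#' Linear voxel-weight classifier
#'
#' A trained linear decision rule: one weight per feature (voxel), a bias,
#' and the fixed sign convention that the pathological class lies on the
#' negative side of the hyperplane. When a `feature_mask` volume is given,
#' the weights correspond, in linear index order, to the `TRUE` voxels of
#' that mask and the classifier can be applied directly to [voxel_image]s.
#'
#' @param weights Numeric weight vector with positive Euclidean norm.
#' @param bias Scalar bias; the decision value is `w . x + b`.
#' @param feature_mask Optional logical volume with `sum(feature_mask) ==
#'   length(weights)`.
#' @return An object of class `linear_classifier`.
#' @export
linear_classifier <- function(weights, bias, feature_mask = NULL) {
  weights <- as.numeric(weights)
  if (!all(is.finite(weights)) || sqrt(sum(weights^2)) == 0) {
    stop("classifier weights must be finite with positive norm")
  }
  if (!is.null(feature_mask) && sum(feature_mask) != length(weights)) {
    stop("weight count must equal the number of voxels in `feature_mask`")
  }
  structure(
    list(weights = weights, bias = as.numeric(bias), feature_mask = feature_mask,
         sign_convention = "pathological_negative"),
    class = "linear_classifier"
  )
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat("<linear_classifier> ", length(x$weights), " weights, |w| = ",
      signif(sqrt(sum(x$weights^2)), 4), ", bias = ", signif(x$bias, 4),
      " (pathological = negative side)\n", sep = "")
  invisible(x)
}

# Exact bias given the optimal weight vector: the primal objective in b
# alone is piecewise-linear convex in the hinge losses; its minimizing
# interval is found over the breakpoints g_i = y_i - f_i and the midpoint
# is returned (for separable data this is the canonical max-margin bias,
# equidistant from the closest points of both classes). Doing it this way
# avoids classifying alphas as bound/free, which is fragile near the box.
svm_bias <- function(f0, y) {
  g <- y - f0
  bs <- sort(unique(g))
  k <- length(bs)
  # slope of the hinge sum on the open interval right of bs[j] (bs[0] = -Inf)
  slope <- function(j) {
    left <- if (j >= 1) sum(y == -1 & g <= bs[j]) else 0
    right <- if (j < k) sum(y == 1 & g >= bs[j + 1]) else 0
    left - right
  }
  j <- 0
  while (j <= k && slope(j) <= 0) j <- j + 1  # first interval sloping up
  if (j >= 1 && slope(j - 1) == 0) (bs[j - 1] + bs[j]) / 2 else bs[j]
}

# Active-set refinement of a near-optimal dual solution to machine
# precision. The numeric solver's alphas carry an O(ridge)/conditioning
# bias; starting from its bound classification, the exact KKT system is
# solved on the free set, box violators are moved to their bound and bound
# alphas with wrong-signed multipliers are released, one (worst) move per
# iteration. Falls back to the input if the system degenerates or the
# refined point is worse.
svm_polish_alpha <- function(Q, y, alpha0, C, max_iter = 60L) {
  n <- length(y)
  tol_a <- 1e-5 * max(alpha0)
  state <- ifelse(alpha0 <= tol_a, 0L, ifelse(alpha0 >= C - tol_a, 1L, 2L))
  alpha <- alpha0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    free <- which(state == 2L); upper <- which(state == 1L)
    if (length(free)) {
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]), c(y[free], 0))
      qterm <- if (length(upper))
        as.numeric(Q[free, upper, drop = FALSE] %*% rep(C, length(upper)))
      else rep(0, length(free))
      rhs <- c(rep(1, length(free)) - qterm, -C * sum(y[upper]))
      ref <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(ref)) break
      af <- ref[seq_along(free)]
      b_mult <- ref[length(ref)]
      viol_lo <- pmax(0, -af); viol_hi <- pmax(0, af - C)
      if (max(viol_lo, viol_hi) > 1e-10 * max(1, max(abs(af)))) {
        worst <- which.max(pmax(viol_lo, viol_hi))
        state[free[worst]] <- if (viol_lo[worst] >= viol_hi[worst]) 0L else 1L
        next
      }
      alpha[] <- 0; alpha[upper] <- C; alpha[free] <- pmin(C, pmax(0, af))
    } else {
      alpha[] <- 0; alpha[upper] <- C
      if (abs(sum(alpha * y)) > 1e-12 * n * C) break
      # multiplier interval for the equality constraint (see svm_bias)
      grad <- as.numeric(Q %*% alpha) - 1
      low <- which(state == 0L)
      lo_set <- c(-grad[low][y[low] > 0], grad[upper][y[upper] < 0])
      hi_set <- c(grad[low][y[low] < 0], -grad[upper][y[upper] > 0])
      lo <- if (length(lo_set)) max(lo_set) else -Inf
      hi <- if (length(hi_set)) min(hi_set) else Inf
      if (lo > hi + 1e-9) break
      b_mult <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
        else if (is.finite(lo)) lo else hi
    }
    # KKT multiplier signs at the bounds
    grad <- as.numeric(Q %*% alpha) - 1
    mu <- grad + b_mult * y
    slack <- numeric(n)
    low <- which(state == 0L)
    slack[low] <- pmax(0, -mu[low])       # need mu >= 0 at alpha = 0
    slack[upper] <- pmax(0, mu[upper])    # need mu <= 0 at alpha = C
    if (max(slack) > 1e-9) {
      state[which.max(slack)] <- 2L
      next
    }
    converged <- TRUE
    break
  }
  dual_obj <- function(a) 0.5 * sum(a * (Q %*% a)) - sum(a)
  if (!converged && (abs(sum(alpha * y)) > 1e-8 * n * C ||
                     dual_obj(alpha) > dual_obj(alpha0) + 1e-12 * n)) {
    return(alpha0)
  }
  alpha
}

# Soft-margin linear C-SVM solved exactly in the dual on a precomputed Gram
# matrix (Goldfarb-Idnani active-set QP). `positive` marks the pathological
# class, coded y = -1 so that pathological cases fall on the negative
# decision side by construction. A tiny ridge keeps the dual strictly
# convex when the Gram matrix is rank-deficient (duplicate or collinear
# cases); it perturbs the solution far below test tolerances.
fit_svm_dual <- function(K, positive, C = 1) {
  positive <- as.logical(positive)
  n <- length(positive)
  if (nrow(K) != n || ncol(K) != n) stop("Gram matrix does not match labels")
  if (n < 2 || !any(positive) || all(positive)) {
    stop("both classes must be present with at least two cases")
  }
  y <- ifelse(positive, -1, 1)
  Q <- (y %o% y) * K
  ridge <- 1e-10 * mean(diag(K)) + 1e-12
  sol <- quadprog::solve.QP(Q + diag(ridge, n), rep(1, n),
                            cbind(y, diag(n), -diag(n)),
                            c(0, rep(0, n), rep(-C, n)), meq = 1)
  alpha <- pmin(C, pmax(0, sol$solution))
  # polish: re-solve the stationarity system exactly on the free set,
  # removing the O(ridge) bias; alphas that land outside the box are moved
  # to their bound and the system is re-solved (a short active-set
  # refinement seeded by the solver's answer)
  alpha <- svm_polish_alpha(Q, y, alpha, C)
  coefs <- alpha * y
  f0 <- as.numeric(K %*% coefs)
  b <- svm_bias(f0, y)
  sv <- which(alpha > 1e-9 * max(alpha, C))
  list(sv = sv, coefs = coefs[sv], b = b, alpha = alpha,
       decision_train = f0 + b)
}

# decision values for new cases given their kernel rows against the
# training set (n_new x n_train); negative = pathological
svm_dual_decision <- function(fit, K_new_train) {
  as.numeric(K_new_train[, fit$sv, drop = FALSE] %*% fit$coefs) + fit$b
}

#' Fit a linear SVM on a feature matrix
#'
#' Soft-margin linear support vector machine with box constraint `C = 1`
#' and no feature standardization, solved exactly in the dual by an
#' active-set quadratic program (the optimum is unique for these data, so
#' any convergent solver agrees). The hyperplane is oriented so that
#' pathological cases fall on the negative decision side.
#'
#' @param features Case-by-feature numeric matrix.
#' @param positive Logical vector: `TRUE` for the pathological class. Both
#'   classes must be present.
#' @param C Box constraint (default 1).
#' @param feature_mask Optional logical volume describing the voxel layout
#'   of the feature columns (passed through to the classifier).
#' @param gram Optional precomputed `tcrossprod(features)`.
#' @return A [linear_classifier()].
#' @export
fit_linear_svm <- function(features, positive, C = 1, feature_mask = NULL,
                           gram = NULL) {
  features <- as.matrix(features)
  if (is.null(gram)) gram <- tcrossprod(features)
  fit <- fit_svm_dual(gram, positive, C = C)
  w <- as.numeric(crossprod(features[fit$sv, , drop = FALSE], fit$coefs))
  linear_classifier(w, fit$b, feature_mask)
}

# feature vector of an image restricted to the classifier's mask
classifier_features <- function(clf, x) {
  if (inherits(x, "voxel_image")) {
    if (is.null(clf$feature_mask)) {
      stop("classifier has no feature mask; supply a numeric feature vector")
    }
    x <- x$values[clf$feature_mask]
  }
  x <- as.numeric(x)
  if (length(x) != length(clf$weights)) {
    stop("image does not cover the classifier's feature mask")
  }
  x
}

#' Signed geometric distance to the hyperplane
#'
#' `d = (w . x + b) / ||w||`. A negative distance corresponds to a
#' pathological (amyloid-positive) case, a positive distance to a normal
#' case; the magnitude measures the strength of evidence.
#'
#' @param clf A [linear_classifier()].
#' @param x A [voxel_image] (its values at the classifier's feature mask
#'   are used) or a numeric feature vector.
#' @return Signed scalar distance.
#' @export
distance_to_hyperplane <- function(clf, x) {
  stopifnot(inherits(clf, "linear_classifier"))
  v <- classifier_features(clf, x)
  nw <- sqrt(sum(clf$weights^2))
  if (nw == 0) stop("zero-norm weight vector")
  (sum(clf$weights * v) + clf$bias) / nw
}

#' Classify a case
#'
#' Pathological iff the signed distance is strictly negative; a case
#' exactly on the hyperplane (`d = 0`) is assigned to the normal class.
#'
#' @inheritParams distance_to_hyperplane
#' @return `"positive"` (pathological) or `"negative"`.
#' @export
classify <- function(clf, x) {
  if (distance_to_hyperplane(clf, x) < 0) "positive" else "negative"
}

#' Confusion-matrix performance metrics
#'
#' Specificity `TN / (TN + FP)`, sensitivity `TP / (TP + FN)` and accuracy
#' `(TP + TN) / N`, reported in percent. If the truth lacks one class the
#' corresponding undefined rate is returned as `NA` (flagged absent rather
#' than NaN-propagated).
#'
#' @param predicted_positive Logical vector of predictions (`TRUE` =
#'   pathological).
#' @param truth_positive Logical vector of ground-truth labels.
#' @return List with `specificity`, `sensitivity`, `accuracy` (percent).
#' @export
confusion_metrics <- function(predicted_positive, truth_positive) {
  p <- as.logical(predicted_positive); t <- as.logical(truth_positive)
  if (length(p) != length(t) || length(p) == 0) {
    stop("predictions and truth must be non-empty and the same length")
  }
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  list(
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    accuracy = 100 * (tp + tn) / length(p)
  )
}

#' Mean classifier of an ensemble
#'
#' Componentwise arithmetic mean of the weight vectors and biases of a set
#' of classifiers sharing one feature mask. Weights are averaged raw
#' (un-normalized).
#'
#' @param classifiers Non-empty list of [linear_classifier()] objects with
#'   identical feature masks.
#' @return A [linear_classifier()].
#' @export
mean_classifier <- function(classifiers) {
  if (length(classifiers) == 0) stop("need at least one classifier")
  masks <- lapply(classifiers, `[[`, "feature_mask")
  if (!all(vapply(masks, identical, logical(1), y = masks[[1]]))) {
    stop("classifiers have inconsistent feature masks")
  }
  W <- matrix(unlist(lapply(classifiers, `[[`, "weights")),
              ncol = length(classifiers))
  w <- rowMeans(W)
  b <- mean(vapply(classifiers, `[[`, numeric(1), "bias"))
  linear_classifier(w, b, masks[[1]])
}

#' Select the top-weight voxels of a classifier
#'
#' Returns the voxels carrying the largest absolute feature weights:
#' `round(fraction * n)` of the `n` mask voxels, ties broken by ascending
#' linear voxel index.
#'
#' @param clf A [linear_classifier()].
#' @param fraction Fraction of voxels to keep, in (0, 1]; default 0.10.
#' @return A logical volume (same shape as the feature mask) when the
#'   classifier has one, otherwise a logical vector over the features.
#' @export
top_fraction_mask <- function(clf, fraction = 0.10) {
  stopifnot(inherits(clf, "linear_classifier"))
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]")
  }
  n <- length(clf$weights)
  k <- round(fraction * n)
  keep <- utils::head(order(-abs(clf$weights), seq_len(n)), k)
  sel <- logical(n)
  sel[keep] <- TRUE
  if (is.null(clf$feature_mask)) {
    return(sel)
  }
  out <- array(FALSE, dim(clf$feature_mask))
  out[which(clf$feature_mask)[sel]] <- TRUE
  out
}

#' Serialize a classifier (NIfTI weight map + JSON sidecar)
#'
#' The weight map is written as a NIfTI volume over the feature mask; bias,
#' weight norm and sign convention travel in a JSON sidecar.
#'
#' @param clf A [linear_classifier()] with a feature mask.
#' @param path NIfTI file path for the weight map.
#' @param spacing Voxel spacing of the weight map (mm).
#' @export
write_classifier <- function(clf, path, spacing = c(4, 4, 4)) {
  stopifnot(inherits(clf, "linear_classifier"))
  if (is.null(clf$feature_mask)) stop("classifier has no feature mask to serialize")
  vol <- array(0, dim(clf$feature_mask))
  vol[clf$feature_mask] <- clf$weights
  nii <- RNifti::asNifti(vol)
  RNifti::pixdim(nii) <- spacing
  RNifti::writeNifti(nii, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(
    list(bias = clf$bias, norm = sqrt(sum(clf$weights^2)),
         sign_convention = clf$sign_convention),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  nii <- RNifti::readNifti(path)
  vol <- array(as.numeric(nii), dim(nii))
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mask <- vol != 0
  linear_classifier(vol[mask], meta$bias, mask)
}
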