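# child seed for ensemble repeat r (distinct stream from subject seeds)
repeat_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(r)) %% 2147483647)
}

#' Balanced-subsample leave-one-out linear-SVM ensemble
#'
#' The central training procedure. Class imbalance is handled by balanced
#' resampling: in each of `n_repeats` repeats the majority class is
#' randomly subsampled (uniformly, without replacement) down to the size of
#' the minority class. Within the balanced set, every case is held out once
#' and predicted by a linear SVM fit on the remaining balanced cases
#' (leave-one-out); the surplus majority-class cases left out of the
#' balanced set are predicted by the model fit on the full balanced set.
#' Each repeat therefore predicts every cohort case exactly once, and
#' specificity, sensitivity and accuracy are computed per repeat over the
#' whole cohort. The repeat classifiers (fit on the full balanced set) are
#' averaged componentwise into the mean classifier.
#'
#' @param features Case-by-feature numeric matrix (e.g. SUVR values over
#'   the brain mask).
#' @param positive Logical vector: `TRUE` marks the pathological class.
#'   The minority class must have at least 3 cases.
#' @param n_repeats Number of balanced resampling repeats (default 50).
#' @param master_seed Integer seed; repeat `r` draws its subsample under
#'   the child seed `(master_seed + 104729 * r) mod (2^31 - 1)`.
#' @param C SVM box constraint (default 1).
#' @param feature_mask Optional logical volume describing the voxel layout
#'   of the feature columns.
#' @return An object of class `ensemble_result`: `repeats` (list with the
#'   subsampled ids, per-repeat [linear_classifier()], per-case predictions
#'   and metrics), `summary` (a `confusion_summary`), `mean_classifier`,
#'   and `balanced_class_size`.
#' @export
balanced_loo_ensemble <- function(features, positive, n_repeats = 50,
                                  master_seed = 1L, C = 1,
                                  feature_mask = NULL) {
  features <- as.matrix(features)
  positive <- as.logical(positive)
  n <- nrow(features)
  if (length(positive) != n) stop("labels do not match the feature matrix")
  n_pos <- sum(positive); n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  m <- min(n_pos, n_neg)
  if (m < 3) stop("minority class has fewer than 3 cases; leave-one-out is degenerate")
  minority <- if (n_pos <= n_neg) which(positive) else which(!positive)
  majority <- setdiff(seq_len(n), minority)
  gram <- tcrossprod(features)

  repeats <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    subsample <- sort(with_seed(repeat_seed(master_seed, r), {
      sample(majority, m, replace = FALSE)
    }))
    balanced <- sort(c(minority, subsample))
    surplus <- setdiff(majority, subsample)
    pred <- logical(n)
    # leave-one-out within the balanced set
    for (i in seq_along(balanced)) {
      train <- balanced[-i]
      held <- balanced[i]
      fit <- fit_svm_dual(gram[train, train, drop = FALSE], positive[train], C = C)
      d <- svm_dual_decision(fit, gram[held, train, drop = FALSE])
      pred[held] <- d < 0
    }
    # full balanced-set model: surplus predictions + the repeat classifier
    full <- fit_svm_dual(gram[balanced, balanced, drop = FALSE],
                         positive[balanced], C = C)
    if (length(surplus)) {
      d <- svm_dual_decision(full, gram[surplus, balanced, drop = FALSE])
      pred[surplus] <- d < 0
    }
    w <- as.numeric(
      crossprod(features[balanced[full$sv], , drop = FALSE], full$coefs))
    clf <- linear_classifier(w, full$b, feature_mask)
    repeats[[r]] <- list(
      subsample = subsample, classifier = clf, predicted_positive = pred,
      metrics = confusion_metrics(pred, positive)
    )
  }
  structure(
    list(
      repeats = repeats,
      summary = confusion_summary(lapply(repeats, `[[`, "metrics")),
      mean_classifier = mean_classifier(lapply(repeats, `[[`, "classifier")),
      balanced_class_size = m,
      n_repeats = n_repeats,
      master_seed = as.integer(master_seed)
    ),
    class = "ensemble_result"
  )
}

#' Summarize per-repeat confusion metrics
#'
#' Mean, SD and a normal-theory 95% confidence interval of the mean
#' (`mean +/- t[0.975, n-1] * SD / sqrt(n)`) for specificity, sensitivity
#' and accuracy across ensemble repeats.
#'
#' @param metrics_list List of per-repeat metric lists as returned by
#'   [confusion_metrics()].
#' @return An object of class `confusion_summary`: a data.frame with one
#'   row per metric and columns mean, sd, ci_lower, ci_upper (percent).
#' @export
confusion_summary <- function(metrics_list) {
  nrep <- length(metrics_list)
  rows <- lapply(c("specificity", "sensitivity", "accuracy"), function(metric) {
    x <- vapply(metrics_list, function(mt) as.numeric(mt[[metric]]), numeric(1))
    mn <- mean(x); s <- stats::sd(x)
    half <- if (nrep > 1) stats::qt(0.975, nrep - 1) * s / sqrt(nrep) else NA_real_
    data.frame(metric = metric, mean = mn, sd = s,
               ci_lower = mn - half, ci_upper = mn + half)
  })
  structure(do.call(rbind, rows), class = c("confusion_summary", "data.frame"))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$n_repeats, " repeats, ",
      x$balanced_class_size, " cases per balanced class\n", sep = "")
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
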