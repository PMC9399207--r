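#' SUVR images of a whole cohort
#'
#' Normalizes every raw cohort image by the mean of the reference region
#' (cerebellar grey matter by default).
#'
#' @param cohort A `phantom_cohort`.
#' @param reference Reference region name.
#' @return List of SUVR [voxel_image]s in subject order.
#' @export
cohort_suvr <- function(cohort, reference = "cerebellar_gm") {
  stopifnot(inherits(cohort, "phantom_cohort"))
  ref_mask <- region_mask(cohort$atlas, reference)
  lapply(cohort$images, compute_suvr, reference_mask = ref_mask)
}

#' Case-by-voxel feature matrix
#'
#' Stacks image values at the `TRUE` voxels of `mask` into the matrix the
#' SVM ensemble consumes (one row per subject, voxels in linear index
#' order).
#'
#' @param images List of [voxel_image]s on a common grid.
#' @param mask Logical volume.
#' @return Numeric matrix, `length(images)` x `sum(mask)`.
#' @export
feature_matrix <- function(images, mask) {
  t(vapply(images, function(img) {
    if (!identical(dim(img$values), dim(mask))) stop("image/mask grid mismatch")
    img$values[mask]
  }, numeric(sum(mask))))
}

# distances of all rows of a feature matrix under a classifier
matrix_distances <- function(clf, X) {
  nw <- sqrt(sum(clf$weights^2))
  as.numeric(X %*% clf$weights + clf$bias) / nw
}

#' Default study configuration
#'
#' All tunable parameters of the synthetic study replica in one list:
#' phantom grid and signal model, cohort compositions, ensemble settings,
#' Centiloid calibrations, and the staging read-surrogate thresholds.
#'
#' @param master_seed Master seed from which every random stream in the
#'   study is derived.
#' @return A nested list; pass it (possibly modified) to [run_study()].
#' @export
default_study_config <- function(master_seed = 1L) {
  list(
    master_seed = as.integer(master_seed),
    grid_dims = c(40, 48, 40),
    spacing = 4,
    model = list(),                       # overrides for signal_model()
    eol_composition = "table1",
    asym_composition = "asymptomatic",
    n_repeats = 50,
    select_fraction = 0.10,
    calibrations = c("mri_assisted", "pet_only"),
    staging = list(cortical_threshold = 0.6, striatal_threshold = 0.7,
                   thal_strict_caudate = FALSE)
  )
}

#' Train the four classifiers on an end-of-life-like cohort
#'
#' Runs the balanced-subsample leave-one-out ensemble against both
#' neuropathological Standards of Truth (Bielschowsky plaque density and
#' dichotomized amyloid phase), derives the two mean classifiers, restricts
#' the features to the 10% of brain-mask voxels with the largest absolute
#' mean weights, and re-runs both ensembles on that selection, yielding the
#' four classifiers original/select x BSS/phase. Also regresses the
#' distance to the hyperplane on maximal plaque density and on amyloid
#' phase, with Welch ANOVA plus Bonferroni-corrected pairwise Welch t-tests
#' across phases.
#'
#' @param cohort An end-of-life-like `phantom_cohort`.
#' @param config A [default_study_config()] list.
#' @return A `training_result` list: `classifiers` (the four mean
#'   classifiers), `ensembles`, `summaries`, `distance_stats`, `labels`,
#'   plus the shared `mask` and feature matrix `X` for reuse downstream.
#' @export
run_training_phase <- function(cohort, config = default_study_config()) {
  labels <- label_cohort(cohort)
  mask <- atlas_brain_mask(cohort$atlas)
  suvr <- cohort_suvr(cohort)
  X <- feature_matrix(suvr, mask)
  bss_pos <- labels$bss_label == "abnormal"
  phase_pos <- labels$phase_label == "high"
  seed <- config$master_seed

  ens <- list(
    original_bss = balanced_loo_ensemble(
      X, bss_pos, n_repeats = config$n_repeats, master_seed = seed + 1L,
      feature_mask = mask),
    original_phase = balanced_loo_ensemble(
      X, phase_pos, n_repeats = config$n_repeats, master_seed = seed + 2L,
      feature_mask = mask)
  )
  select_masks <- list(
    bss = top_fraction_mask(ens$original_bss$mean_classifier, config$select_fraction),
    phase = top_fraction_mask(ens$original_phase$mean_classifier, config$select_fraction)
  )
  ens$select_bss <- balanced_loo_ensemble(
    X[, select_masks$bss[mask], drop = FALSE], bss_pos,
    n_repeats = config$n_repeats, master_seed = seed + 3L,
    feature_mask = select_masks$bss)
  ens$select_phase <- balanced_loo_ensemble(
    X[, select_masks$phase[mask], drop = FALSE], phase_pos,
    n_repeats = config$n_repeats, master_seed = seed + 4L,
    feature_mask = select_masks$phase)

  classifiers <- lapply(ens, `[[`, "mean_classifier")
  d_phase <- matrix_distances(classifiers$original_phase, X)
  phase_groups <- split(d_phase, labels$amyloid_phase)
  distance_stats <- list(
    distance_vs_cerad = correlations(labels$cerad_max,
                                     matrix_distances(classifiers$original_bss, X)),
    distance_vs_phase = correlations(labels$amyloid_phase, d_phase),
    welch_across_phases = welch_anova(phase_groups),
    pairwise_welch = pairwise_welch_bonferroni(phase_groups)
  )
  structure(
    list(classifiers = classifiers, ensembles = ens,
         summaries = lapply(ens, `[[`, "summary"),
         select_masks = select_masks, distance_stats = distance_stats,
         labels = labels, mask = mask, X = X, atlas = cohort$atlas,
         config = config),
    class = "training_result"
  )
}

#' Transfer the trained classifiers to an asymptomatic-like cohort
#'
#' Applies all four classifiers to the transfer cohort, quantifies every
#' subject on the Centiloid scale under the requested calibrations, and
#' produces per-classifier distance-vs-CL Pearson/Spearman correlations,
#' the Dunn & Clark comparison of the BSS- and phase-based correlations
#' (original pair and select pair), and the ROC of CL against the
#' predicted label with its Youden cut-off.
#'
#' @param training A `training_result`.
#' @param cohort An asymptomatic-like `phantom_cohort` on the same grid.
#' @param config Study configuration (for the calibration arms).
#' @return A `transfer_result` list: `per_subject` data.frame (id, CL per
#'   arm, distances and predictions per classifier), `correlations`,
#'   `correlation_comparisons`, `roc`.
#' @export
run_transfer_phase <- function(training, cohort,
                               config = training$config) {
  stopifnot(inherits(training, "training_result"))
  if (!identical(dim(cohort$atlas$labels), dim(training$mask))) {
    stop("transfer cohort is not on the training grid")
  }
  suvr <- cohort_suvr(cohort)
  X <- feature_matrix(suvr, training$mask)
  tab <- subject_table(cohort)
  suvr_comp <- vapply(suvr, composite_suvr, numeric(1), atlas = cohort$atlas)
  cls <- vapply(config$calibrations, function(tag) {
    suvr_to_centiloid(suvr_comp, centiloid_calibration(tag))
  }, numeric(length(suvr_comp)))
  colnames(cls) <- config$calibrations

  distances <- lapply(training$classifiers, function(clf) {
    if (is.null(clf$feature_mask) || identical(clf$feature_mask, training$mask)) {
      matrix_distances(clf, X)
    } else {
      matrix_distances(clf, X[, clf$feature_mask[training$mask], drop = FALSE])
    }
  })
  per_subject <- cbind(
    data.frame(id = tab$id, suvr_comp = suvr_comp),
    stats::setNames(as.data.frame(cls), paste0("cl_", config$calibrations)),
    stats::setNames(as.data.frame(distances),
                    paste0("distance_", names(distances))),
    stats::setNames(as.data.frame(lapply(distances, function(d) d < 0)),
                    paste0("positive_", names(distances)))
  )

  cors <- list(); rocs <- list()
  for (arm in config$calibrations) {
    cl <- cls[, arm]
    for (nm in names(distances)) {
      key <- paste(arm, nm, sep = ".")
      cors[[key]] <- correlations(distances[[nm]], cl)
      pred <- distances[[nm]] < 0
      rocs[[key]] <- if (any(pred) && !all(pred)) {
        roc_youden(cl, pred, positive_direction = "higher")
      } else NULL
    }
  }
  comparisons <- lapply(config$calibrations, function(arm) {
    cl <- cls[, arm]
    list(
      original = compare_overlapping_correlations(
        cl, distances$original_bss, distances$original_phase),
      select = compare_overlapping_correlations(
        cl, distances$select_bss, distances$select_phase)
    )
  })
  names(comparisons) <- config$calibrations
  structure(
    list(per_subject = per_subject, correlations = cors, roc = rocs,
         correlation_comparisons = comparisons),
    class = "transfer_result"
  )
}

#' Score every classifier against the alternative ground truth
#'
#' Each mean classifier is applied to the full training cohort and scored
#' both against its own Standard of Truth and against the alternative one
#' (plaque-density-trained classifiers against the phase labels and vice
#' versa).
#'
#' @param training A `training_result`.
#' @return Data.frame with one row per (classifier, truth) pair and the
#'   confusion metrics in percent.
#' @export
run_cross_truth_evaluation <- function(training) {
  stopifnot(inherits(training, "training_result"))
  labels <- training$labels
  truths <- list(bss = labels$bss_label == "abnormal",
                 phase = labels$phase_label == "high")
  rows <- list()
  for (nm in names(training$classifiers)) {
    clf <- training$classifiers[[nm]]
    Xc <- if (identical(clf$feature_mask, training$mask)) training$X else
      training$X[, clf$feature_mask[training$mask], drop = FALSE]
    pred <- matrix_distances(clf, Xc) < 0
    for (truth_nm in names(truths)) {
      mt <- confusion_metrics(pred, truths[[truth_nm]])
      rows[[paste(nm, truth_nm)]] <- data.frame(
        classifier = nm, truth = truth_nm,
        specificity = mt$specificity, sensitivity = mt$sensitivity,
        accuracy = mt$accuracy, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relate the distance to the hyperplane to PET amyloid staging
#'
#' Computes per-subject PET amyloid stages under both threshold schemes
#' (from pons-referenced SUVRs with threshold-based read surrogates),
#' tests whether the distance to the hyperplane differs across stages
#' (Kruskal-Wallis, then pairwise Mann-Whitney with Bonferroni
#' correction), and cross-tabulates the stages against the dichotomized
#' neuropathological phase.
#'
#' @param training A `training_result`.
#' @param cohort The end-of-life-like cohort (raw images are needed for
#'   the pons reference).
#' @param classifier Which classifier's distances to use (default the
#'   phase-trained original classifier).
#' @return A `staging_result` list: `per_subject`, `kruskal`, `pairwise`
#'   (Bonferroni-adjusted Mann-Whitney p per stage pair), `cross_tabs`.
#' @export
run_staging_comparison <- function(training, cohort,
                                   classifier = "original_phase") {
  stopifnot(inherits(training, "training_result"))
  cfg <- training$config$staging
  inputs <- lapply(cohort$images, staging_input_from_image,
                   atlas = cohort$atlas,
                   cortical_threshold = cfg$cortical_threshold,
                   striatal_threshold = cfg$striatal_threshold)
  thal <- vapply(inputs, thal_pet_stage, integer(1),
                 strict_caudate = isTRUE(cfg$thal_strict_caudate))
  hans <- vapply(inputs, function(inp) {
    hanseeuw_stage(inp$cortical_positive, inp$striatal_positive)
  }, integer(1))
  clf <- training$classifiers[[classifier]]
  Xc <- if (identical(clf$feature_mask, training$mask)) training$X else
    training$X[, clf$feature_mask[training$mask], drop = FALSE]
  d <- matrix_distances(clf, Xc)
  per_subject <- data.frame(
    id = training$labels$id, amyloid_phase = training$labels$amyloid_phase,
    phase_label = training$labels$phase_label,
    thal_stage = thal, hanseeuw_stage = hans, distance = d,
    read_surrogate = TRUE, stringsAsFactors = FALSE)

  stage_tests <- function(stage) {
    groups <- split(d, stage)
    groups <- groups[lengths(groups) >= 1]
    kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
    pairs <- list()
    nms <- names(groups)
    if (length(groups) >= 2) {
      for (i in seq_len(length(groups) - 1)) {
        for (j in (i + 1):length(groups)) {
          pairs[[paste(nms[i], nms[j], sep = "_vs_")]] <-
            mann_whitney(groups[[i]], groups[[j]])$p
        }
      }
      m <- length(pairs)
      pairs <- lapply(pairs, function(p) min(1, m * p))
    }
    list(kruskal = kw, pairwise_bonferroni = pairs)
  }
  structure(
    list(per_subject = per_subject,
         thal = stage_tests(thal), hanseeuw = stage_tests(hans),
         cross_tabs = list(
           thal_vs_phase_label = table(thal = thal, phase = per_subject$phase_label),
           hanseeuw_vs_phase_label = table(hanseeuw = hans,
                                           phase = per_subject$phase_label))),
    class = "staging_result"
  )
}

#' Run the complete synthetic study replica
#'
#' Generates the phantom atlas and both cohorts, trains the four
#' classifiers on the end-of-life-like cohort, transfers them to the
#' asymptomatic-like cohort, scores the cross-ground-truth performance and
#' the staging comparison, and (optionally) writes all per-subject tables
#' and statistics to `out_dir`. The run is a pure function of the
#' configuration: identical config and master seed give byte-identical
#' outputs.
#'
#' @param config A [default_study_config()] list (possibly modified).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `study_report` list with `training`, `transfer`,
#'   `cross_truth`, `staging`, and the cohorts' label tables.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL) {
  atlas <- generate_atlas(config$grid_dims, config$spacing)
  model <- do.call(signal_model, config$model)
  eol <- generate_cohort(atlas, config$eol_composition, model,
                         master_seed = config$master_seed)
  asym <- generate_cohort(atlas, config$asym_composition, model,
                          master_seed = config$master_seed + 5000L)
  training <- run_training_phase(eol, config)
  transfer <- run_transfer_phase(training, asym, config)
  cross_truth <- run_cross_truth_evaluation(training)
  staging <- run_staging_comparison(training, eol)
  report <- structure(
    list(training = training, transfer = transfer, cross_truth = cross_truth,
         staging = staging, eol_labels = label_cohort(eol),
         asym_labels = label_cohort(asym), config = config),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

summaries_frame <- function(summaries) {
  out <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- as.data.frame(summaries[[nm]])
    s$classifier <- nm
    s
  }))
  out[, c("classifier", "metric", "mean", "sd", "ci_lower", "ci_upper")]
}

#' Write a study report to disk
#'
#' Emits the per-subject tables as CSV and the statistics as JSON; the
#' effective configuration is copied verbatim into the directory as YAML.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$eol_labels, file.path(out_dir, "subjects_eol.csv"),
                   row.names = FALSE)
  utils::write.csv(report$asym_labels, file.path(out_dir, "subjects_asym.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries_frame(report$training$summaries),
                   file.path(out_dir, "training_summary.csv"), row.names = FALSE)
  utils::write.csv(report$transfer$per_subject,
                   file.path(out_dir, "transfer_per_subject.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cross_truth,
                   file.path(out_dir, "cross_truth.csv"), row.names = FALSE)
  utils::write.csv(report$staging$per_subject,
                   file.path(out_dir, "staging_per_subject.csv"),
                   row.names = FALSE)
  stats_out <- list(
    distance_stats = report$training$distance_stats[
      c("distance_vs_cerad", "distance_vs_phase", "welch_across_phases")],
    transfer_correlations = lapply(report$transfer$correlations,
                                   function(co) co[c("pearson_r", "spearman_rho",
                                                     "slope", "n")]),
    correlation_comparisons = lapply(report$transfer$correlation_comparisons,
                                     function(arm) lapply(arm, unclass)),
    roc = lapply(report$transfer$roc, function(r) {
      if (is.null(r)) NULL else
        r[c("auc", "best_threshold", "specificity", "sensitivity")]
    }),
    staging_tests = list(thal = report$staging$thal,
                         hanseeuw = report$staging$hanseeuw)
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(report$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
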