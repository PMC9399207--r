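#' Binarize CERAD neuritic plaque density (Bielschowsky Standard of Truth)
#'
#' A case is abnormal when at least one regional mean neuritic plaque
#' density score exceeds 1.5 (strict inequality: a density of exactly 1.5
#' in every region is still negative).
#'
#' @param regional_densities Numeric vector of per-region mean neuritic
#'   plaque density scores on the 0-3 scale (non-empty).
#' @return `"abnormal"` or `"normal"`.
#' @export
binarize_cerad <- function(regional_densities) {
  d <- as.numeric(regional_densities)
  if (length(d) == 0) stop("empty density list")
  if (any(!is.finite(d)) || any(d < 0 | d > 3)) {
    stop("regional densities must be finite values in [0, 3]")
  }
  if (max(d) > 1.5) "abnormal" else "normal"
}

#' Dichotomize the amyloid phase
#'
#' Phases 0-2 are grouped as `"low"` and contrasted with phases 3-5
#' (`"high"`), matching the convention that phases 0-2 are not detectable
#' in vivo with amyloid PET.
#'
#' @param amyloid_phase Integer 0-5 (vectorized).
#' @return `"low"` or `"high"` per element.
#' @export
binarize_phase <- function(amyloid_phase) {
  p <- as.numeric(amyloid_phase)
  if (any(!is.finite(p)) || any(p != floor(p)) || any(p < 0 | p > 5)) {
    stop("amyloid phase must be an integer in 0..5")
  }
  ifelse(p <= 2, "low", "high")
}

#' Label a cohort under both Standards of Truth
#'
#' @param cohort A `phantom_cohort`.
#' @return The [subject_table()] of the cohort with added columns
#'   `bss_label` (`normal`/`abnormal`) and `phase_label` (`low`/`high`).
#' @export
label_cohort <- function(cohort) {
  tab <- subject_table(cohort)
  tab$bss_label <- vapply(cohort$subjects, function(s) {
    binarize_cerad(s$cerad_regional_densities)
  }, character(1))
  tab$phase_label <- binarize_phase(tab$amyloid_phase)
  tab
}
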