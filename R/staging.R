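#' Inputs for PET amyloid staging
#'
#' Pons-referenced semi-quantitative SUVRs of the cortex and caudate
#' nucleus plus the boolean read surrogates the two staging schemes need.
#' This module never emulates a human reader: the booleans are inputs
#' (the pipeline derives them by thresholding phantom SUVRs and marks them
#' as surrogates).
#'
#' @param suvr_cortex_pons Cortical SUVR with the pons as reference
#'   (>= 0).
#' @param suvr_caudate_pons Caudate SUVR with the pons as reference
#'   (>= 0).
#' @param visible_retention Whether tracer retention is visible at all
#'   (visual-read surrogate).
#' @param cortical_positive,striatal_positive Binary cortical/striatal
#'   positivity (read surrogates).
#' @return An object of class `staging_input`.
#' @export
staging_input <- function(suvr_cortex_pons, suvr_caudate_pons,
                          visible_retention = FALSE,
                          cortical_positive = FALSE,
                          striatal_positive = FALSE) {
  if (suvr_cortex_pons < 0 || suvr_caudate_pons < 0) {
    stop("staging SUVRs must be non-negative")
  }
  structure(
    list(suvr_cortex_pons = as.numeric(suvr_cortex_pons),
         suvr_caudate_pons = as.numeric(suvr_caudate_pons),
         visible_retention = isTRUE(visible_retention),
         cortical_positive = isTRUE(cortical_positive),
         striatal_positive = isTRUE(striatal_positive)),
    class = "staging_input"
  )
}

#' Four-level PET amyloid phase estimate (threshold scheme)
#'
#' Semi-quantitative staging from pons-referenced cortical and caudate
#' SUVRs. The published rules are disjunctive and overlap: estimate 1
#' requires `SUVR_cortex >= 0.5` and/or `SUVR_caudate >= 0.6`; estimate 2
#' `SUVR_cortex >= 0.6` and/or `SUVR_caudate >= 0.7`; estimate 3
#' `SUVR_cortex >= 0.6` and/or `SUVR_caudate >= 1.0`. The highest
#' satisfied rule wins; estimate 0 is returned when no rule fires and no
#' retention is visible. Because the cortical threshold 0.6 appears in
#' both the estimate-2 and estimate-3 rules, the literal reading lets
#' cortex alone reach estimate 3; `strict_caudate = TRUE` instead requires
#' `SUVR_caudate >= 1.0` for estimate 3, surfacing rather than silently
#' resolving the ambiguity.
#'
#' @param inp A [staging_input()].
#' @param strict_caudate Require the caudate criterion for estimate 3
#'   (default `FALSE`, the literal reading).
#' @return Integer stage 0-3.
#' @export
thal_pet_stage <- function(inp, strict_caudate = FALSE) {
  stopifnot(inherits(inp, "staging_input"))
  cortex <- inp$suvr_cortex_pons; caudate <- inp$suvr_caudate_pons
  e1 <- cortex >= 0.5 || caudate >= 0.6
  e2 <- cortex >= 0.6 || caudate >= 0.7
  e3 <- if (strict_caudate) caudate >= 1.0 else (cortex >= 0.6 || caudate >= 1.0)
  if (e3) return(3L)
  if (e2) return(2L)
  if (e1) return(1L)
  if (inp$visible_retention) return(1L)
  0L
}

#' Three-level PET amyloid stage (read-based scheme)
#'
#' Stage 0: low cortical and low striatal signal; stage 1: high cortical,
#' low striatal; stage 2: high cortical and high striatal. The fourth cell
#' (striatal-positive but cortical-negative) is not defined by the scheme
#' and raises an error.
#'
#' @param cortical_positive,striatal_positive Logical scalars.
#' @return Integer stage 0-2.
#' @export
hanseeuw_stage <- function(cortical_positive, striatal_positive) {
  c_pos <- isTRUE(as.logical(cortical_positive))
  s_pos <- isTRUE(as.logical(striatal_positive))
  if (!c_pos && s_pos) {
    stop("invalid combination: striatal-positive with cortical-negative is not a defined stage")
  }
  if (c_pos && s_pos) 2L else if (c_pos) 1L else 0L
}

#' Staging inputs for a phantom subject
#'
#' Computes the pons-referenced cortical (composite VOI) and caudate SUVRs
#' of an image and derives the read surrogates by thresholding: cortical
#' positivity at `cortical_threshold`, striatal positivity at
#' `striatal_threshold`, visible retention when either semi-quantitative
#' value reaches its estimate-1 threshold. These surrogates stand in for
#' human visual reads and are flagged as such in pipeline output.
#'
#' @param img A raw or SUVR [voxel_image] (the pons normalization is
#'   applied internally, so any positive scaling of the input cancels).
#' @param atlas The phantom atlas.
#' @param cortical_threshold,striatal_threshold Pons-referenced SUVR
#'   thresholds for the read surrogates.
#' @return A [staging_input()].
#' @export
staging_input_from_image <- function(img, atlas, cortical_threshold = 0.6,
                                     striatal_threshold = 0.7) {
  pons_suvr <- compute_suvr(img, region_mask(atlas, "pons"))
  cortex <- masked_mean(pons_suvr, region_mask(atlas, composite_regions()))
  caudate <- masked_mean(pons_suvr, region_mask(atlas, "caudate"))
  cortical_positive <- cortex >= cortical_threshold
  staging_input(
    suvr_cortex_pons = cortex,
    suvr_caudate_pons = caudate,
    visible_retention = cortex >= 0.5 || caudate >= 0.6,
    cortical_positive = cortical_positive,
    # the read-based scheme has no cell for striatal-only positivity; the
    # surrogate counts striatal signal only in cortical-positive cases
    striatal_positive = cortical_positive && caudate >= striatal_threshold
  )
}
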