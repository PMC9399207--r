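#' SUVR normalization
#'
#' Divides every voxel by the mean value inside the reference mask
#' (cerebellar grey matter by default in this pipeline; the pons is used
#' for the staging inputs). The reference mean of the output is exactly 1.
#'
#' @param img A [voxel_image] of raw uptake.
#' @param reference_mask Logical array selecting the reference region; its
#'   mean must be strictly positive.
#' @return A [voxel_image] of SUVR values.
#' @export
compute_suvr <- function(img, reference_mask) {
  stopifnot(inherits(img, "voxel_image"))
  ref <- masked_mean(img, reference_mask)
  if (!is.finite(ref) || ref <= 0) {
    stop("reference-region mean must be strictly positive")
  }
  voxel_image(img$values / ref, img$spacing, img$brain_mask)
}

#' Composite volume of interest
#'
#' The composite VOI over which the global amyloid burden is quantified:
#' by default the five bilateral cortical regions (frontal, parietal,
#' anterior cingulate, posterior cingulate, lateral temporal).
#'
#' @param members Character vector of member region names (non-empty).
#' @return An object of class `composite_voi`.
#' @export
composite_voi <- function(members = composite_regions()) {
  members <- as.character(members)
  if (length(members) == 0) stop("composite VOI must have at least one member region")
  structure(list(members = members), class = "composite_voi")
}

#' Composite SUVR
#'
#' Mean SUVR over the union of the member regions of the composite VOI.
#'
#' @param suvr_img A [voxel_image] of SUVR values.
#' @param atlas The phantom atlas defining the regions.
#' @param voi A [composite_voi()] (default: the five cortical regions).
#' @return Scalar composite SUVR.
#' @export
composite_suvr <- function(suvr_img, atlas, voi = composite_voi()) {
  stopifnot(inherits(voi, "composite_voi"))
  masked_mean(suvr_img, region_mask(atlas, voi$members))
}

#' Centiloid calibration
#'
#' The affine conversion from composite SUVR to the Centiloid scale. Two
#' published calibrations are built in: the MRI-assisted processing arm,
#' `CL = 127.6 * SUVR_comp - 149`, and the PET-only arm,
#' `CL = 210.49 * SUVR_comp - 250.13`.
#'
#' @param pipeline_tag `"mri_assisted"` or `"pet_only"`, or `"custom"` when
#'   slope/intercept are given directly.
#' @param slope,intercept Conversion coefficients (slope must be positive);
#'   ignored unless `pipeline_tag = "custom"`.
#' @return An object of class `centiloid_calibration`.
#' @export
centiloid_calibration <- function(pipeline_tag = c("mri_assisted", "pet_only", "custom"),
                                  slope = NULL, intercept = NULL) {
  pipeline_tag <- match.arg(pipeline_tag)
  if (pipeline_tag == "mri_assisted") {
    slope <- 127.6; intercept <- -149
  } else if (pipeline_tag == "pet_only") {
    slope <- 210.49; intercept <- -250.13
  } else if (is.null(slope) || is.null(intercept)) {
    stop("custom calibration needs explicit slope and intercept")
  }
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 pipeline_tag = pipeline_tag),
            class = "centiloid_calibration")
}

#' @export
print.centiloid_calibration <- function(x, ...) {
  cat(sprintf("<centiloid_calibration> CL = %.4g * SUVR_comp + %.4g (%s)\n",
              x$slope, x$intercept, x$pipeline_tag))
  invisible(x)
}

#' Convert composite SUVR to Centiloids
#'
#' @param suvr_comp Numeric vector of composite SUVR values.
#' @param cal A [centiloid_calibration()].
#' @return `cal$slope * suvr_comp + cal$intercept`.
#' @export
suvr_to_centiloid <- function(suvr_comp, cal = centiloid_calibration("mri_assisted")) {
  stopifnot(inherits(cal, "centiloid_calibration"))
  cal$slope * as.numeric(suvr_comp) + cal$intercept
}

#' Calibrate a Centiloid conversion by linear regression
#'
#' Ordinary least squares of reference Centiloid values on composite SUVR,
#' mirroring how a local processing pipeline is anchored to the standard
#' Centiloid method on a calibration dataset.
#'
#' @param suvr_comp Numeric vector of composite SUVR values (at least two
#'   distinct values).
#' @param reference_cl Reference Centiloid values of the same length.
#' @return A `centiloid_calibration` with `pipeline_tag = "custom"`.
#' @export
calibrate_centiloid <- function(suvr_comp, reference_cl) {
  x <- as.numeric(suvr_comp); y <- as.numeric(reference_cl)
  if (length(x) != length(y) || length(x) < 2) {
    stop("need at least two (SUVR, CL) pairs")
  }
  if (length(unique(x)) < 2) {
    stop("degenerate design: all SUVR values are equal")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  centiloid_calibration("custom", slope = fit$coefficients[2],
                        intercept = fit$coefficients[1])
}

#' Serialize a calibration as JSON
#' @param cal A `centiloid_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "centiloid_calibration"))
  jsonlite::write_json(cal[c("slope", "intercept", "pipeline_tag")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centiloid_calibration("custom", slope = x$slope, intercept = x$intercept)
}
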