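#' Phantom region names
#'
#' The eleven regions of the phantom atlas: the five cortical regions of the
#' composite VOI used for Centiloid quantification (frontal, parietal,
#' anterior and posterior cingulate, lateral temporal), the precuneus and
#' caudate (striatal signal for staging), the two candidate reference
#' regions (cerebellar grey matter, pons), white matter (nonspecific
#' retention) and background.
#'
#' @return Character vector of region names in label order (background is
#'   label 0).
#' @export
phantom_regions <- function() {
  c("frontal", "parietal", "anterior_cingulate", "posterior_cingulate",
    "lateral_temporal", "precuneus", "caudate", "cerebellar_gm", "pons",
    "white_matter")
}

#' Names of the composite-VOI cortical regions
#' @return Character vector of the five composite regions.
#' @export
composite_regions <- function() {
  c("frontal", "parietal", "anterior_cingulate", "posterior_cingulate",
    "lateral_temporal")
}

# index range of a fractional interval [lo, hi] on an axis of n voxels;
# guaranteed non-empty for hi - lo >= 1/n
frac_idx <- function(lo, hi, n) {
  i0 <- floor(lo * n) + 1L
  i1 <- ceiling(hi * n)
  i0 <- max(1L, min(i0, n))
  i1 <- max(1L, min(i1, n))
  if (i1 < i0) i1 <- i0
  i0:i1
}

# region boxes in fractional grid coordinates: list(name = list(u, v, w))
# u = left-right, v = posterior-anterior, w = inferior-superior.
# Claim order matters: earlier regions win overlapping voxels.
phantom_region_boxes <- function() {
  list(
    precuneus           = list(u = c(0.40, 0.60), v = c(0.25, 0.40), w = c(0.72, 0.90)),
    caudate             = list(u = c(0.38, 0.62), v = c(0.52, 0.66), w = c(0.42, 0.56)),
    anterior_cingulate  = list(u = c(0.42, 0.58), v = c(0.58, 0.74), w = c(0.55, 0.76)),
    posterior_cingulate = list(u = c(0.42, 0.58), v = c(0.36, 0.52), w = c(0.55, 0.70)),
    frontal             = list(u = c(0.15, 0.85), v = c(0.70, 0.94), w = c(0.42, 0.86)),
    parietal            = list(u = c(0.15, 0.85), v = c(0.25, 0.55), w = c(0.70, 0.94)),
    lateral_temporal_l  = list(u = c(0.04, 0.24), v = c(0.35, 0.75), w = c(0.33, 0.56)),
    lateral_temporal_r  = list(u = c(0.76, 0.96), v = c(0.35, 0.75), w = c(0.33, 0.56)),
    cerebellar_gm       = list(u = c(0.30, 0.70), v = c(0.05, 0.28), w = c(0.05, 0.26)),
    pons                = list(u = c(0.40, 0.60), v = c(0.30, 0.43), w = c(0.05, 0.23)),
    white_matter        = list(u = c(0.22, 0.78), v = c(0.22, 0.80), w = c(0.34, 0.80))
  )
}

#' Generate the phantom atlas
#'
#' Builds a deterministic integer label volume on the requested grid. The
#' regions are axis-aligned boxes placed in fractional grid coordinates and
#' claimed in a fixed priority order, so every non-background voxel carries
#' exactly one label, the cerebellar grey matter and pons are disjoint from
#' all cortical regions (they sit in the inferior posterior compartment),
#' and the same arguments always return the same atlas. Realistic brain
#' geometry is explicitly out of scope: the atlas exists to give every
#' downstream stage structurally correct region masks.
#'
#' @param grid_dims Integer vector of length 3; each entry must be `>= 16`
#'   so that every region box spans at least one voxel.
#' @param spacing Voxel spacing in mm (scalar or length 3). Default 4 mm
#'   isotropic.
#' @return An object of class `phantom_atlas` with fields `labels` (integer
#'   array, 0 = background), `spacing`, and `region_table` (data.frame of
#'   id, name, n_voxels).
#' @export
generate_atlas <- function(grid_dims = c(40, 48, 40), spacing = 4) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(is.na(grid_dims))) {
    stop("`grid_dims` must be three integers")
  }
  if (any(grid_dims < 16L)) {
    stop("configuration error: each grid dimension must be >= 16 to place all regions")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  labels <- array(0L, grid_dims)
  boxes <- phantom_region_boxes()
  regions <- phantom_regions()
  id_of <- stats::setNames(seq_along(regions), regions)
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    region <- sub("_[lr]$", "", nm)
    ui <- frac_idx(b$u[1], b$u[2], grid_dims[1])
    vi <- frac_idx(b$v[1], b$v[2], grid_dims[2])
    wi <- frac_idx(b$w[1], b$w[2], grid_dims[3])
    blk <- labels[ui, vi, wi]
    blk[blk == 0L] <- id_of[[region]]
    labels[ui, vi, wi] <- blk
  }
  counts <- tabulate(labels[labels > 0L], nbins = length(regions))
  structure(
    list(
      labels = labels,
      spacing = as.numeric(spacing),
      region_table = data.frame(
        id = seq_along(regions), name = regions, n_voxels = counts,
        stringsAsFactors = FALSE
      )
    ),
    class = "phantom_atlas"
  )
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat("<phantom_atlas> ", paste(dim(x$labels), collapse = " x "),
      " @ ", paste(x$spacing, collapse = "x"), " mm\n", sep = "")
  print(x$region_table, row.names = FALSE)
  invisible(x)
}

#' Region mask lookup
#'
#' @param atlas A `phantom_atlas`.
#' @param regions Character vector of region names; the mask is the union
#'   of the named regions.
#' @return Logical array over the atlas grid.
#' @export
region_mask <- function(atlas, regions) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  unknown <- setdiff(regions, atlas$region_table$name)
  if (length(unknown)) {
    stop("configuration error: unknown region(s): ", paste(unknown, collapse = ", "))
  }
  ids <- atlas$region_table$id[match(regions, atlas$region_table$name)]
  array(atlas$labels %in% ids, dim(atlas$labels))
}

#' Brain mask of an atlas (all non-background voxels)
#' @param atlas A `phantom_atlas`.
#' @return Logical array.
#' @export
atlas_brain_mask <- function(atlas) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  array(atlas$labels > 0L, dim(atlas$labels))
}

#' Write/read a phantom atlas as NIfTI
#'
#' The label volume is stored as a NIfTI image; the region table travels in
#' a JSON sidecar written next to it (same path with extension `.json`).
#'
#' @param atlas A `phantom_atlas`.
#' @param path NIfTI file path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  nii <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(nii) <- atlas$spacing
  RNifti::writeNifti(nii, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(atlas$region_table, sidecar, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  nii <- RNifti::readNifti(path)
  labels <- array(as.integer(nii), dim(nii))
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  region_table <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  structure(
    list(labels = labels, spacing = RNifti::pixdim(nii)[1:3],
         region_table = region_table),
    class = "phantom_atlas"
  )
}
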