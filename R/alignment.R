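#' Voxel-grid geometry
#'
#' A minimal affine geometry: voxel indices (1-based) map to world
#' coordinates in mm through `world = (index - 1) * voxel_size + origin`
#' (axis-aligned), or through an arbitrary 4x4 affine supplied directly.
#'
#' @param shape Integer triple of voxel counts.
#' @param voxel_size Voxel edge lengths in mm.
#' @param origin World coordinates of the first voxel's centre.
#' @param affine Optional 4x4 affine overriding `voxel_size`/`origin`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, voxel_size = c(1, 1, 1),
                          origin = c(0, 0, 0), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) .stop_invalid("'shape' must be 3 positive integers")
  if (is.null(affine)) {
    if (any(voxel_size <= 0)) .stop_invalid("'voxel_size' must be positive")
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin - voxel_size  # world of index (1,1,1) is origin
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4, 4))) .stop_invalid("'affine' must be 4x4")
  }
  structure(list(shape = shape, affine = affine), class = "grid_geometry")
}

#' Resample a binary mask onto a target grid
#'
#' Nearest-neighbour resampling of a label/binary image between two voxel
#' grids with known affine geometries.  Nearest-neighbour interpolation
#' preserves binarity and is the conventional choice for label images.
#'
#' @param mask 3D logical (or 0/1) array on the source grid.
#' @param source_geometry,target_geometry [grid_geometry()] objects.
#' @return Logical array with the target shape.  If the two fields of view
#'   do not overlap, an all-`FALSE` mask is returned with a warning.
#' @export
resample_mask <- function(mask, source_geometry, target_geometry) {
  if (!inherits(source_geometry, "grid_geometry") ||
      !inherits(target_geometry, "grid_geometry"))
    .stop_invalid("geometries must be 'grid_geometry' objects")
  if (!all(dim(mask) == source_geometry$shape))
    .stop_invalid("'mask' does not match the source geometry shape")
  ts <- target_geometry$shape
  idx <- arrayInd(seq_len(prod(ts)), ts)
  # target index -> world -> source index
  M <- solve(source_geometry$affine) %*% target_geometry$affine
  src <- cbind(idx, 1) %*% t(M)
  si <- round(src[, 1:3])
  ok <- si[, 1] >= 1 & si[, 1] <= dim(mask)[1] &
        si[, 2] >= 1 & si[, 2] <= dim(mask)[2] &
        si[, 3] >= 1 & si[, 3] <= dim(mask)[3]
  out <- array(FALSE, dim = ts)
  if (!any(ok)) {
    warning("source and target fields of view do not overlap; returning empty mask")
    return(out)
  }
  lin <- si[ok, 1] + (si[ok, 2] - 1) * dim(mask)[1] +
    (si[ok, 3] - 1) * dim(mask)[1] * dim(mask)[2]
  out[ok] <- as.logical(mask[lin])
  out
}

#' Evaluable voxel set of a study
#'
#' The evaluation mask is the intersection of the CTP coverage mask with
#' the map set's valid-voxel mask.  All confusion counts, overlap scores
#' and ROC points are restricted to it: brain regions not covered by CTP
#' never enter the comparison with the final infarct volume.
#'
#' @param study A `ctp_study`.
#' @param map_set A `ctp_map_set` computed from the same study.
#' @return Logical 3D array.  An empty evaluable set is a fatal error.
#' @export
make_eval_mask <- function(study, map_set) {
  if (!all(dim(study$coverage_mask) == dim(map_set$valid_mask)))
    .stop_invalid("study and map set shapes disagree")
  ev <- study$coverage_mask & map_set$valid_mask
  if (!any(ev)) .stop_invalid("empty evaluation mask: no valid voxels inside coverage")
  ev
}
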