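# NIfTI import/export built on RNifti; geometry is carried through pixdim.

#' Write a synthetic subject as NIfTI files
#'
#' Writes the 4D study (`<id>_ctp.nii.gz`), the truth masks and the true
#' parameter maps as 3D volumes, plus the coverage mask.
#'
#' @param subject A `ctp_subject`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_subject <- function(subject, dir) {
  if (!inherits(subject, "ctp_subject")) .stop_invalid("'subject' must be a 'ctp_subject'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- subject$study
  id <- st$subject_id
  paths <- character(0)
  wr <- function(arr, suffix, pixdim) {
    p <- file.path(dir, paste0(id, "_", suffix, ".nii.gz"))
    img <- RNifti::`pixdim<-`(RNifti::asNifti(arr + 0), pixdim)
    RNifti::writeNifti(img, p)
    paths <<- c(paths, p)
  }
  wr(st$data, "ctp", c(st$voxel_size, st$dt))
  wr(st$coverage_mask, "coverage", st$voxel_size)
  tr <- subject$truth
  wr(tr$fiv_mask_true, "fiv", st$voxel_size)
  for (nm in c("cbf", "cbv", "mtt", "delay"))
    if (!is.null(tr[[nm]])) wr(tr[[nm]], paste0("true-", nm), st$voxel_size)
  invisible(paths)
}

#' Write a parametric map set as NIfTI files
#'
#' One 3D volume per parameter (`<id>_<ALGO>_<param>.nii.gz`) plus the
#' valid mask.
#'
#' @param map_set A `ctp_map_set`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_map_set <- function(map_set, dir) {
  if (!inherits(map_set, "ctp_map_set")) .stop_invalid("'map_set' must be a 'ctp_map_set'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- if (is.null(map_set$subject_id)) "sub" else map_set$subject_id
  paths <- character(0)
  wr3 <- function(arr, suffix) {
    p <- file.path(dir, paste0(id, "_", map_set$algorithm, "_", suffix, ".nii.gz"))
    img <- RNifti::`pixdim<-`(RNifti::asNifti(arr + 0), map_set$voxel_size)
    RNifti::writeNifti(img, p)
    p
  }
  for (nm in intersect(.CTP_PARAMETERS, names(map_set)))
    paths <- c(paths, wr3(map_set[[nm]], nm))
  invisible(c(paths, wr3(map_set$valid_mask, "valid")))
}

#' Read a 4D CTP study from NIfTI
#'
#' @param path NIfTI file with a 4D volume.
#' @param group Subject group, `"A"` or `"B"`.
#' @param subject_id Character label.
#' @param dt Temporal sampling in seconds; `NULL` takes the 4th pixdim.
#' @param coverage Optional coverage mask NIfTI path; `NULL` means full
#'   coverage.
#' @return A `ctp_study`.
#' @export
read_ctp_study <- function(path, group = c("A", "B"), subject_id = "sub-001",
                           dt = NULL, coverage = NULL) {
  group <- match.arg(group)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) .stop_invalid("expected a 4D CTP volume in ", path)
  pd <- RNifti::pixdim(img)
  if (is.null(dt)) dt <- if (length(pd) >= 4) pd[4] else .stop_invalid("supply 'dt'")
  voxel_size <- pd[1:3]
  cov <- if (is.null(coverage)) array(TRUE, dim = dim(arr)[1:3]) else read_mask(coverage)
  structure(list(data = arr, dt = dt, voxel_size = voxel_size,
                 coverage_mask = cov, subject_id = subject_id, group = group,
                 times = (seq_len(dim(arr)[4]) - 1) * dt, aif_true = NULL),
            class = "ctp_study")
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file; any non-zero voxel is `TRUE`.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3) .stop_invalid("expected a 3D mask in ", path)
  arr != 0
}
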