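#' Extract an arterial input curve from a study
#'
#' Returns the baseline-subtracted, non-negative concentration curve at a
#' voxel (optionally averaged over an in-plane neighbourhood to suppress
#' noise), or processes a curve supplied directly by the caller (the
#' synthetic mode passes the true AIF).
#'
#' @param study A `ctp_study`.
#' @param location Either an integer voxel index triple inside the coverage
#'   mask, or a numeric vector of length `n_timepoints` taken as the curve
#'   itself.
#' @param baseline_window Number of leading timepoints whose mean is
#'   subtracted.
#' @param neighborhood In-plane half-width: `1` averages the 3x3 voxel
#'   neighbourhood around `location`, `0` uses the single voxel.
#' @return Concentration vector.
#' @export
extract_aif_curve <- function(study, location, baseline_window = 4L,
                              neighborhood = 0L) {
  if (!inherits(study, "ctp_study")) .stop_invalid("'study' must be a 'ctp_study'")
  nt <- dim(study$data)[4]
  if (is.numeric(location) && length(location) == nt && nt != 3) {
    curve <- as.numeric(location)
  } else {
    if (length(location) != 3) .stop_invalid("'location' must be a voxel index triple or a curve")
    loc <- as.integer(location)
    gs <- dim(study$data)[1:3]
    if (any(loc < 1) || any(loc > gs)) .stop_invalid("'location' outside the grid")
    if (!study$coverage_mask[loc[1], loc[2], loc[3]])
      .stop_invalid("'location' outside the coverage mask")
    r <- as.integer(neighborhood)
    xs <- max(1, loc[1] - r):min(gs[1], loc[1] + r)
    ys <- max(1, loc[2] - r):min(gs[2], loc[2] + r)
    block <- study$data[xs, ys, loc[3], , drop = FALSE]
    curve <- apply(array(block, dim = c(length(xs) * length(ys), nt)), 2, mean)
  }
  k <- min(baseline_window, length(curve))
  base <- mean(curve[seq_len(k)])
  out <- pmax(curve - base, 0)
  if (max(out) <= 1e-12 * max(1, abs(base)))
    .stop_invalid("no bolus: curve maximum does not exceed the baseline")
  out
}

# edge-aware in-plane 3x3 boxcar smoothing of a 4D array
.smooth_inplane <- function(data) {
  d <- dim(data)
  out <- array(0, dim = d)
  cnt <- array(0, dim = d[1:2])
  acc <- array(0, dim = d[1:2])
  for (z in seq_len(d[3])) {
    for (t in seq_len(d[4])) {
      sl <- data[, , z, t]
      acc[] <- 0; cnt[] <- 0
      for (dx in -1:1) for (dy in -1:1) {
        xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy
        okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
        acc[okx, oky] <- acc[okx, oky] + sl[xs[okx], ys[oky]]
        cnt[okx, oky] <- cnt[okx, oky] + 1
      }
      out[, , z, t] <- acc / cnt
    }
  }
  out
}

# pooled noise estimate: median over voxels of the baseline-window sd
.estimate_noise <- function(curves, baseline_window) {
  k <- min(baseline_window, nrow(curves))
  if (k < 2) return(0)
  stats::median(apply(curves[seq_len(k), , drop = FALSE], 2, sd))
}

#' Compute a parametric map set for one study
#'
#' Runs the configured deconvolution at every voxel inside the coverage
#' mask and assembles the CBF/CBV/MTT volumes plus the timing map native to
#' the algorithm (TTP for ATS, Tmax for ATI).  Voxels outside coverage or
#' with degenerate curves (non-positive estimated flow or volume) are
#' flagged invalid and carry `NA`.
#'
#' @param study A `ctp_study`.
#' @param aif AIF concentration curve (e.g. from [extract_aif_curve()], or
#'   the phantom's true AIF).
#' @param config A [deconv_config()].
#' @return An object of class `ctp_map_set`: algorithm label, map volumes
#'   (`cbf`, `cbv`, `mtt`, and `ttp` or `tmax`), `valid_mask`, and the
#'   study geometry.  Contralateral-relative maps are added by
#'   [compute_relative_maps()].
#' @export
compute_map_set <- function(study, aif, config = deconv_config()) {
  if (!inherits(study, "ctp_study")) .stop_invalid("'study' must be a 'ctp_study'")
  if (!inherits(config, "deconv_config")) .stop_invalid("'config' must be a 'deconv_config'")
  gs <- dim(study$data)[1:3]
  nt <- dim(study$data)[4]
  if (length(aif) != nt) .stop_invalid("'aif' length must match the study timepoints")
  if (sum(aif) <= 0) .stop_invalid("degenerate input: zero AIF area")
  cov <- study$coverage_mask
  if (!any(cov)) .stop_invalid("empty coverage mask")

  data <- if (config$smooth) .smooth_inplane(study$data) else study$data
  vox <- which(cov)
  nvox <- prod(gs)
  curves <- matrix(0, nt, length(vox))
  for (ti in seq_len(nt)) curves[ti, ] <- data[vox + (ti - 1) * nvox]
  # per-voxel baseline subtraction
  k <- min(config$baseline_window, nt)
  base <- colMeans(curves[seq_len(k), , drop = FALSE])
  curves <- sweep(curves, 2, base)

  sn <- if (is.null(config$noise_sd)) .estimate_noise(curves, config$baseline_window)
        else config$noise_sd

  if (config$algorithm == "ATS") {
    A <- .conv_matrix_causal(aif, study$dt)
    K <- .tsvd_solve(A, curves, config$truncation_fraction, sn, nt)
  } else {
    A <- .conv_matrix_circulant(aif, study$dt, config$padding_factor)
    K <- .tsvd_solve(A, rbind(curves, matrix(0, nrow(A) - nt, ncol(curves))),
                     config$truncation_fraction, sn, nt)
  }
  est <- .residue_estimates(K, curves, aif, study$dt, config$cbf_scale)

  valid_v <- is.finite(est$cbf) & est$cbf > 0 & est$cbv > 0
  blank <- array(NA_real_, dim = gs)
  fill <- function(vals) { m <- blank; m[vox[valid_v]] <- vals[valid_v]; m }
  valid <- array(FALSE, dim = gs)
  valid[vox[valid_v]] <- TRUE

  maps <- list(cbf = fill(est$cbf), cbv = fill(est$cbv), mtt = fill(est$mtt))
  if (config$algorithm == "ATS") {
    ttp_v <- study$dt * (max.col(t(curves), ties.method = "first") - 1)
    maps$ttp <- fill(ttp_v)
  } else {
    maps$tmax <- fill(est$tmax)
  }
  structure(c(list(algorithm = config$algorithm), maps,
              list(valid_mask = valid, dt = study$dt,
                   voxel_size = study$voxel_size,
                   subject_id = study$subject_id, noise_sd = sn)),
            class = "ctp_map_set")
}

#' Add contralateral-relative maps to a map set
#'
#' For every parametric map, the relative map divides each voxel's value by
#' the value at the mirrored voxel of the other hemisphere (exact index
#' flip about the midline sagittal plane; the grid's x-dimension must be
#' even).  Voxels whose mirror is invalid or whose mirror value is at or
#' below `epsilon` are invalid in the relative map.
#'
#' @param map_set A `ctp_map_set`.
#' @param epsilon Smallest admissible mirror denominator.
#' @return The map set with `cbf_rel`, `cbv_rel`, `mtt_rel` and
#'   `tmax_rel`/`ttp_rel` volumes added.
#' @export
compute_relative_maps <- function(map_set, epsilon = 1e-6) {
  if (!inherits(map_set, "ctp_map_set")) .stop_invalid("'map_set' must be a 'ctp_map_set'")
  base_names <- intersect(c("cbf", "cbv", "mtt", "tmax", "ttp"), names(map_set))
  nx <- dim(map_set$valid_mask)[1]
  if (nx %% 2 != 0) .stop_invalid("x-dimension must be even for an exact mirror")
  mirror <- function(v) v[nx:1, , , drop = FALSE]
  for (nm in base_names) {
    v <- map_set[[nm]]
    vm <- mirror(v)
    rel <- v / vm
    rel[!is.finite(rel) | vm <= epsilon] <- NA_real_
    map_set[[paste0(nm, "_rel")]] <- rel
  }
  map_set
}

#' Fetch a parameter volume from a map set
#'
#' @param map_set A `ctp_map_set`.
#' @param parameter One of the map names (`"cbf"`, `"cbv"`, `"mtt"`,
#'   `"tmax"`, `"ttp"` or a `"_rel"` variant).
#' @return The 3D volume (`NA` where invalid).
#' @export
map_parameter <- function(map_set, parameter) {
  parameter <- match.arg(parameter, .CTP_PARAMETERS)
  if (is.null(map_set[[parameter]]))
    .stop_invalid("map set (", map_set$algorithm, ") has no '", parameter,
                  "' map; relative maps require compute_relative_maps()")
  map_set[[parameter]]
}

#' @export
print.ctp_map_set <- function(x, ...) {
  nms <- intersect(.CTP_PARAMETERS, names(x))
  cat("CTP map set [", x$algorithm, "] maps:", paste(nms, collapse = ", "), "\n")
  cat("  valid voxels:", sum(x$valid_mask), "/", length(x$valid_mask), "\n")
  invisible(x)
}
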