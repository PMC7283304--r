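#' Gamma-variate arterial input function specification
#'
#' The arterial input function (AIF) is modelled as a gamma-variate bolus,
#' \deqn{a(t) = A (t - t_0)^\alpha e^{-(t - t_0)/\beta}, \quad t > t_0,}
#' and zero before bolus arrival at \eqn{t_0}.  The curve peaks at
#' \eqn{t_0 + \alpha\beta}.
#'
#' @param amplitude Positive scale factor, in arbitrary attenuation units.
#' @param t0 Bolus arrival time in seconds (non-negative).
#' @param alpha Dimensionless shape parameter (positive).
#' @param beta Time-scale parameter in seconds (positive).
#' @return An object of class `aif_spec`.
#' @seealso [evaluate_aif()]
#' @export
aif_spec <- function(amplitude = 20, t0 = 8, alpha = 3, beta = 1.5) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
      amplitude <= 0)
    .stop_invalid("'amplitude' must be a positive number")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    .stop_invalid("'beta' must be a positive number")
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    .stop_invalid("'alpha' must be a positive number")
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0) || t0 < 0)
    .stop_invalid("'t0' must be a non-negative number")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta),
            class = "aif_spec")
}

#' Evaluate a gamma-variate AIF on a time grid
#'
#' @param spec An [aif_spec()] object.
#' @param times Non-negative, uniformly spaced sample times in seconds.
#' @return Numeric vector of concentration values (zero for `t <= t0`).
#' @examples
#' a <- aif_spec(amplitude = 1, t0 = 0, alpha = 3, beta = 1.5)
#' evaluate_aif(a, seq(0, 20, by = 2))
#' @export
evaluate_aif <- function(spec, times) {
  if (!inherits(spec, "aif_spec")) .stop_invalid("'spec' must be an 'aif_spec'")
  if (any(times < 0)) .stop_invalid("'times' must be non-negative")
  if (length(times) > 2) {
    d <- diff(times)
    if (max(abs(d - d[1])) > 1e-8 * max(abs(d)))
      .stop_invalid("'times' must be uniformly spaced")
  }
  s <- times - spec$t0
  out <- numeric(length(times))
  pos <- s > 0
  out[pos] <- spec$amplitude * s[pos]^spec$alpha * exp(-s[pos] / spec$beta)
  out
}

#' Tissue region specification for the perfusion phantom
#'
#' Each region carries true cerebral blood flow (CBF), mean transit time
#' (MTT) and bolus-arrival delay.  True cerebral blood volume is always
#' derived through the central volume principle, `CBV = CBF * MTT / 60`,
#' and is never stored independently.
#'
#' @param label One of `"normal"`, `"core"`, `"penumbra"`.
#' @param cbf True CBF in ml/100g/min (positive; `core < penumbra < normal`
#'   is enforced at the phantom level).
#' @param mtt True MTT in seconds (positive).
#' @param delay Bolus-arrival delay relative to the AIF, in seconds
#'   (non-negative).
#' @param center,radii Ellipsoid centre and radii in (1-based) voxel
#'   coordinates for lesion regions; ignored for `"normal"`, which is the
#'   background.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(label, cbf, mtt, delay, center = NULL, radii = NULL) {
  label <- match.arg(label, c("normal", "core", "penumbra"))
  if (!is.numeric(cbf) || cbf <= 0) .stop_invalid("'cbf' must be positive")
  if (!is.numeric(mtt) || mtt <= 0) .stop_invalid("'mtt' must be positive")
  if (!is.numeric(delay) || delay < 0) .stop_invalid("'delay' must be >= 0")
  if (label != "normal") {
    if (is.null(center) || is.null(radii) || length(center) != 3 ||
        length(radii) != 3 || any(radii <= 0))
      .stop_invalid("lesion regions need a 3-vector 'center' and positive 'radii'")
  }
  structure(list(label = label, cbf = cbf, mtt = mtt, delay = delay,
                 center = center, radii = radii),
            class = "region_spec")
}

#' @rdname region_spec
#' @param region A `region_spec`.
#' @return `region_cbv()`: the derived true CBV in ml/100g.
#' @export
region_cbv <- function(region) region$cbf * region$mtt / 60

#' Default phantom regions
#'
#' Normal tissue CBF 60 ml/100g/min, MTT 4 s, no delay; penumbra CBF 25,
#' MTT 7 s, delay 3 s; ischemic core CBF 8, MTT 10 s, delay 6 s.  The core
#' ellipsoid is nested inside the penumbra in the right hemisphere.  These
#' are simulator defaults chosen to respect the orderings the clinical
#' threshold ranges presuppose; they are not measurements.
#'
#' @param grid_shape Integer triple giving the voxel grid the geometry is
#'   scaled to.
#' @return List of three [region_spec()] objects.
#' @export
default_regions <- function(grid_shape = c(32L, 32L, 8L)) {
  cx <- round(grid_shape[1] * 0.75)
  cy <- round(grid_shape[2] / 2)
  cz <- round(grid_shape[3] / 2)
  sc <- grid_shape / c(32, 32, 8)
  list(
    region_spec("normal", cbf = 60, mtt = 4, delay = 0),
    region_spec("penumbra", cbf = 25, mtt = 7, delay = 3,
                center = c(cx, cy, cz), radii = c(6, 7, 3) * sc),
    region_spec("core", cbf = 8, mtt = 10, delay = 6,
                center = c(cx, cy, cz), radii = c(3, 4, 2) * sc)
  )
}

#' Phantom specification
#'
#' Describes one synthetic CTP acquisition: a left-right symmetric voxel
#' grid (even x-dimension, so the contralateral mirror is an exact index
#' flip about the midline sagittal plane), a temporal sampling scheme
#' (default 30 frames at 2 s, i.e. a 60 s scan), tissue regions, a
#' gamma-variate AIF and additive i.i.d. Gaussian noise.
#'
#' The default `noise_sd = 0.5` puts the peak lesion-to-normal curve
#' contrast at roughly five times the noise level.
#'
#' @param grid_shape Integer triple (x, y, z); x must be even.
#' @param voxel_size Voxel edge lengths in mm.
#' @param n_timepoints Number of temporal samples.
#' @param dt Temporal sampling interval in seconds.
#' @param regions List of [region_spec()] objects, exactly one `"normal"`.
#' @param aif An [aif_spec()].
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   concentration (attenuation) units.
#' @param coverage_slices Optional integer range of z-slices inside the
#'   field of view (emulating restricted craniocaudal coverage); `NULL`
#'   means full coverage.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 8L),
                         voxel_size = c(2, 2, 5),
                         n_timepoints = 30L, dt = 2,
                         regions = default_regions(grid_shape),
                         aif = aif_spec(),
                         noise_sd = 0.5,
                         coverage_slices = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    .stop_invalid("'grid_shape' must be three integers >= 2")
  if (grid_shape[1] %% 2 != 0)
    .stop_invalid("'grid_shape[1]' must be even so the midline mirror is exact")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    .stop_invalid("'voxel_size' must be three positive lengths (mm)")
  if (dt <= 0) .stop_invalid("'dt' must be positive")
  if (n_timepoints < 10) .stop_invalid("'n_timepoints' must be >= 10")
  if (noise_sd < 0) .stop_invalid("'noise_sd' must be >= 0")
  labels <- vapply(regions, function(r) r$label, character(1))
  if (sum(labels == "normal") != 1)
    .stop_invalid("'regions' must contain exactly one 'normal' region")
  cbfs <- vapply(regions, function(r) r$cbf, numeric(1))
  if ("core" %in% labels && "penumbra" %in% labels) {
    if (!(cbfs[labels == "core"] < cbfs[labels == "penumbra"] &&
          cbfs[labels == "penumbra"] < cbfs[labels == "normal"]))
      .stop_invalid("true CBF must satisfy core < penumbra < normal")
  }
  if (!is.null(coverage_slices)) {
    coverage_slices <- as.integer(coverage_slices)
    if (any(coverage_slices < 1) || any(coverage_slices > grid_shape[3]))
      .stop_invalid("'coverage_slices' outside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_timepoints = as.integer(n_timepoints), dt = dt,
                 regions = regions, aif = aif, noise_sd = noise_sd,
                 coverage_slices = coverage_slices),
            class = "phantom_spec")
}

#' Simulate a tissue time-attenuation curve
#'
#' Indicator-dilution model: the tissue concentration curve is the discrete
#' convolution (Riemann sum with step `dt`) of the AIF with a scaled,
#' delayed residue function,
#' \deqn{C(t) = \frac{CBF}{6000} [a \circledast R](t - \delta),}
#' with a mono-exponential residue \eqn{R(t) = e^{-t/MTT}} by default, or a
#' boxcar residue (\eqn{R(t) = 1} for \eqn{t < MTT}) for oracle tests.  The
#' delay is rounded to the nearest sample of the `dt` grid before shifting;
#' sub-sample delays are out of scope.
#'
#' @param aif Sampled AIF concentration vector.
#' @param cbf True CBF in ml/100g/min (zero allowed and yields a zero curve).
#' @param mtt True MTT in seconds (positive).
#' @param delay Bolus-arrival delay in seconds (non-negative).
#' @param dt Sampling interval in seconds.
#' @param residue `"exponential"` (default) or `"boxcar"`.
#' @return Concentration vector of the same length as `aif`.
#' @export
simulate_tissue_curve <- function(aif, cbf, mtt, delay, dt,
                                  residue = c("exponential", "boxcar")) {
  residue <- match.arg(residue)
  if (dt <= 0) .stop_invalid("'dt' must be positive")
  if (mtt <= 0) .stop_invalid("'mtt' must be positive")
  if (cbf < 0) .stop_invalid("'cbf' must be >= 0")
  if (delay < 0) .stop_invalid("'delay' must be >= 0")
  n <- length(aif)
  if (cbf == 0) return(numeric(n))
  t <- (seq_len(n) - 1) * dt
  r <- switch(residue,
              exponential = exp(-t / mtt),
              boxcar = as.numeric(t < mtt))
  k <- (cbf / .CBF_SCALE) * r
  d <- as.integer(round(delay / dt))
  kd <- c(numeric(d), k)[seq_len(n)]
  dt * convolve(aif, rev(kd), type = "open")[seq_len(n)]
}

# label every voxel with its region; core overrides penumbra overrides normal
.region_label_map <- function(spec) {
  gs <- spec$grid_shape
  lab <- array("normal", dim = gs)
  idx <- arrayInd(seq_len(prod(gs)), gs)
  for (nm in c("penumbra", "core")) {
    for (r in spec$regions) {
      if (r$label != nm) next
      u <- (idx[, 1] - r$center[1]) / r$radii[1]
      v <- (idx[, 2] - r$center[2]) / r$radii[2]
      w <- (idx[, 3] - r$center[3]) / r$radii[3]
      inside <- u * u + v * v + w * w <= 1
      if (!any(inside)) .stop_invalid("empty lesion region '", nm, "'")
      xs <- range(idx[inside, 1])
      half <- gs[1] / 2
      if (xs[1] <= half && xs[2] > half)
        .stop_invalid("lesion region '", nm, "' crosses the midline")
      if (xs[1] < 1 || xs[2] > gs[1])
        .stop_invalid("lesion region '", nm, "' outside the grid")
      lab[inside] <- nm
    }
  }
  lab
}

#' Build one synthetic CTP subject
#'
#' Simulates every voxel's time-attenuation curve from its region's true
#' perfusion parameters, adds i.i.d. Gaussian noise, and attaches the
#' ground truth.  The ground-truth final infarct volume (FIV) mask is
#' core plus penumbra for group `"A"` (no or failed thrombectomy: the whole
#' hypoperfused territory infarcts) and core only for group `"B"`
#' (successful thrombectomy: the penumbra is salvaged).
#'
#' @param spec A [phantom_spec()].
#' @param group `"A"` or `"B"`.
#' @param subject_id Character label.
#' @param seed Integer seed; identical `spec` + `seed` gives bit-identical
#'   output.
#' @return An object of class `ctp_subject`: a list with elements `study`
#'   (class `ctp_study`: 4D `data`, `dt`, `voxel_size`, `coverage_mask`,
#'   `subject_id`, `group`, `times`, `aif_true`) and `truth` (class
#'   `subject_truth`: `region_label_map`, `fiv_mask_true` and true
#'   `cbf`/`cbv`/`mtt`/`delay` maps).
#' @export
build_subject <- function(spec, group = c("A", "B"), subject_id = "sub-001",
                          seed = 1L) {
  if (!inherits(spec, "phantom_spec")) .stop_invalid("'spec' must be a 'phantom_spec'")
  group <- match.arg(group)
  gs <- spec$grid_shape
  nt <- spec$n_timepoints
  times <- (seq_len(nt) - 1) * spec$dt
  aif <- evaluate_aif(spec$aif, times)

  lab <- .region_label_map(spec)
  pars <- lapply(spec$regions, function(r)
    list(label = r$label, cbf = r$cbf, mtt = r$mtt, delay = r$delay))
  names(pars) <- vapply(pars, `[[`, character(1), "label")

  cbf_map <- array(NA_real_, gs); mtt_map <- cbf_map; delay_map <- cbf_map
  data <- array(0, dim = c(gs, nt))
  nvox <- prod(gs)
  for (nm in names(pars)) {
    sel <- lab == nm
    if (!any(sel)) next
    p <- pars[[nm]]
    cbf_map[sel] <- p$cbf
    mtt_map[sel] <- p$mtt
    delay_map[sel] <- round(p$delay / spec$dt) * spec$dt
    curve <- simulate_tissue_curve(aif, p$cbf, p$mtt, p$delay, spec$dt)
    w <- which(sel)
    for (ti in seq_len(nt)) data[w + (ti - 1) * nvox] <- curve[ti]
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    data <- data + array(rnorm(length(data), 0, spec$noise_sd), dim = dim(data))
  }

  coverage <- array(TRUE, dim = gs)
  if (!is.null(spec$coverage_slices)) {
    coverage[] <- FALSE
    coverage[, , spec$coverage_slices] <- TRUE
  }

  fiv <- if (group == "A") lab == "core" | lab == "penumbra" else lab == "core"

  study <- structure(list(data = data, dt = spec$dt,
                          voxel_size = spec$voxel_size,
                          coverage_mask = coverage,
                          subject_id = subject_id, group = group,
                          times = times, aif_true = aif),
                     class = "ctp_study")
  truth <- structure(list(region_label_map = lab, fiv_mask_true = fiv,
                          cbf = cbf_map, cbv = cbf_map * mtt_map / 60,
                          mtt = mtt_map, delay = delay_map),
                     class = "subject_truth")
  structure(list(study = study, truth = truth, spec = spec, seed = seed),
            class = "ctp_subject")
}

#' Parameter ranges for sampling a synthetic cohort
#'
#' Per-subject true perfusion values are drawn uniformly from these ranges;
#' a degenerate range (equal bounds) pins the parameter.  `size_scale`
#' multiplies the default lesion radii.
#'
#' @param core_cbf,core_mtt,core_delay,pen_cbf,pen_mtt,pen_delay,size_scale
#'   Length-2 numeric ranges `c(min, max)` with `min <= max`.
#' @return An object of class `cohort_sampler`.
#' @export
cohort_sampler <- function(core_cbf = c(6, 12), core_mtt = c(8, 12),
                           core_delay = c(4, 8),
                           pen_cbf = c(18, 30), pen_mtt = c(5, 8),
                           pen_delay = c(2, 4),
                           size_scale = c(0.7, 1.3)) {
  ranges <- list(core_cbf = core_cbf, core_mtt = core_mtt,
                 core_delay = core_delay, pen_cbf = pen_cbf,
                 pen_mtt = pen_mtt, pen_delay = pen_delay,
                 size_scale = size_scale)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      .stop_invalid("invalid range for '", nm, "': need c(min, max) with min <= max")
  }
  structure(ranges, class = "cohort_sampler")
}

# stable derived per-subject seed, kept below 2^31
.subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

#' Build a synthetic cohort
#'
#' Generates `n_a` group-A subjects (no/failed thrombectomy) and `n_b`
#' group-B subjects (successful thrombectomy), the default 25 + 29 matching
#' the reference cohort size of 54.  Each subject's lesion perfusion values
#' and size are drawn from `sampler` with a per-subject seed derived
#' deterministically from `seed`.
#'
#' @param n_a,n_b Number of subjects per group (>= 1).
#' @param sampler A [cohort_sampler()].
#' @param base_spec A [phantom_spec()] providing grid, AIF, noise and the
#'   normal-tissue parameters.
#' @param seed Integer master seed.
#' @return An object of class `ctp_cohort`: a list of `ctp_subject`s with a
#'   `table` attribute (one row per subject: id, group, seed and the drawn
#'   parameters).
#' @export
build_cohort <- function(n_a = 25L, n_b = 29L, sampler = cohort_sampler(),
                         base_spec = phantom_spec(), seed = 1L) {
  if (n_a < 1 || n_b < 1) .stop_invalid("'n_a' and 'n_b' must be >= 1")
  if (!inherits(sampler, "cohort_sampler"))
    .stop_invalid("'sampler' must be a 'cohort_sampler'")
  n <- n_a + n_b
  groups <- c(rep("A", n_a), rep("B", n_b))
  subjects <- vector("list", n)
  tab <- vector("list", n)
  normal <- Filter(function(r) r$label == "normal", base_spec$regions)[[1]]
  defaults <- default_regions(base_spec$grid_shape)
  pen0 <- Filter(function(r) r$label == "penumbra", defaults)[[1]]
  core0 <- Filter(function(r) r$label == "core", defaults)[[1]]
  for (i in seq_len(n)) {
    sseed <- .subject_seed(seed, i)
    set.seed(sseed)
    draw <- vapply(sampler, function(r) runif(1, r[1], r[2]), numeric(1))
    if (draw[["pen_cbf"]] >= normal$cbf)
      .stop_invalid("sampled penumbra CBF must stay below normal CBF")
    regions <- list(
      normal,
      region_spec("penumbra", cbf = draw[["pen_cbf"]], mtt = draw[["pen_mtt"]],
                  delay = draw[["pen_delay"]], center = pen0$center,
                  radii = pen0$radii * draw[["size_scale"]]),
      region_spec("core", cbf = draw[["core_cbf"]], mtt = draw[["core_mtt"]],
                  delay = draw[["core_delay"]], center = core0$center,
                  radii = core0$radii * draw[["size_scale"]])
    )
    spec_i <- phantom_spec(grid_shape = base_spec$grid_shape,
                           voxel_size = base_spec$voxel_size,
                           n_timepoints = base_spec$n_timepoints,
                           dt = base_spec$dt, regions = regions,
                           aif = base_spec$aif, noise_sd = base_spec$noise_sd,
                           coverage_slices = base_spec$coverage_slices)
    id <- sprintf("sub-%03d", i)
    subjects[[i]] <- build_subject(spec_i, groups[i], id, seed = sseed + 1L)
    tab[[i]] <- data.frame(subject_id = id, group = groups[i], seed = sseed,
                           t(draw))
  }
  structure(subjects, class = "ctp_cohort", table = do.call(rbind, tab))
}

#' Planted-threshold cohort
#'
#' A designed experiment for threshold-recovery validation: a cohort whose
#' ground-truth FIV is exactly the set of voxels with true bolus-arrival
#' delay of at least 6 s.  All subjects are group B (FIV = core); core
#' delays ladder deterministically from 6 to 9 s and penumbral delays from
#' 2.5 up to 5.5 s, so the generative Tmax cutoff separating FIV from
#' non-FIV tissue sits between 5.5 and 6 s.  Sampling uses `dt = 0.5` s
#' over the same 60 s duration so that the recovered Tmax resolution
#' matches the 0.5 s threshold-grid increment.
#'
#' @param n Number of subjects (>= 2).
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer master seed (noise only; the design is deterministic).
#' @param grid_shape,voxel_size Spatial grid (kept small; the experiment is
#'   about temporal structure).
#' @return A `ctp_cohort`.
#' @export
planted_delay_cohort <- function(n = 10L, noise_sd = 0, seed = 1L,
                                 grid_shape = c(16L, 16L, 4L),
                                 voxel_size = c(4, 4, 10)) {
  if (n < 2) .stop_invalid("'n' must be >= 2")
  pen_delay <- seq(2.5, 5.5, length.out = n)
  core_delay <- seq(6, 9, length.out = n)
  cx <- round(grid_shape[1] * 0.75); cy <- round(grid_shape[2] / 2)
  cz <- round(grid_shape[3] / 2)
  subjects <- vector("list", n)
  tab <- vector("list", n)
  for (i in seq_len(n)) {
    regions <- list(
      region_spec("normal", cbf = 60, mtt = 4, delay = 0),
      region_spec("penumbra", cbf = 25, mtt = 7, delay = pen_delay[i],
                  center = c(cx, cy, cz), radii = c(3, 4, 1.6)),
      region_spec("core", cbf = 8, mtt = 10, delay = core_delay[i],
                  center = c(cx, cy, cz), radii = c(1.6, 2, 1.1))
    )
    spec_i <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                           n_timepoints = 120L, dt = 0.5, regions = regions,
                           noise_sd = noise_sd)
    id <- sprintf("sub-%03d", i)
    subjects[[i]] <- build_subject(spec_i, "B", id,
                                   seed = .subject_seed(seed, i))
    tab[[i]] <- data.frame(subject_id = id, group = "B",
                           pen_delay = pen_delay[i], core_delay = core_delay[i])
  }
  structure(subjects, class = "ctp_cohort", table = do.call(rbind, tab))
}

#' @export
print.ctp_subject <- function(x, ...) {
  gs <- dim(x$study$data)
  cat("CTP subject", x$study$subject_id, "(group", x$study$group, ")\n")
  cat("  grid:", paste(gs[1:3], collapse = "x"), " timepoints:", gs[4],
      " dt:", x$study$dt, "s\n")
  cat("  FIV voxels:", sum(x$truth$fiv_mask_true), "\n")
  invisible(x)
}

#' @export
print.ctp_cohort <- function(x, ...) {
  tab <- attr(x, "table")
  cat("CTP cohort:", length(x), "subjects (",
      sum(tab$group == "A"), "A /", sum(tab$group == "B"), "B )\n")
  invisible(x)
}
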