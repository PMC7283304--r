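#' Threshold grid for a parametric map
#'
#' An inclusive arithmetic sequence of thresholds, generated by integer
#' index (`minimum + k * increment`) with a half-increment endpoint
#' tolerance so the endpoint is never lost to floating-point drift:
#' `floor((maximum - minimum)/increment) + 1` values.
#'
#' @param parameter One of the ten map names (`"cbv"`, `"mtt"`, `"cbf"`,
#'   `"tmax"`, `"ttp"` or their `"_rel"` variants).
#' @param minimum,maximum Range bounds in the parameter's units
#'   (`minimum < maximum`).
#' @param increment Positive step.
#' @param direction `"above"` (lesion where value exceeds the threshold) or
#'   `"below"`; `NULL` selects the lesion direction conventional for the
#'   parameter (above for the time-based maps, below for flow and volume).
#' @return An object of class `threshold_grid` with a `values` element.
#' @examples
#' length(make_threshold_grid("tmax", 1, 16, 0.5)$values)  # 31
#' @export
make_threshold_grid <- function(parameter, minimum, maximum, increment,
                                direction = NULL) {
  parameter <- match.arg(parameter, .CTP_PARAMETERS)
  if (!is.numeric(minimum) || !is.numeric(maximum) || minimum >= maximum)
    .stop_invalid("invalid grid: need minimum < maximum")
  if (!is.numeric(increment) || increment <= 0)
    .stop_invalid("invalid grid: 'increment' must be positive")
  if (is.null(direction)) direction <- .LESION_DIRECTION[[parameter]]
  direction <- match.arg(direction, c("above", "below"))
  n <- floor((maximum - minimum + increment / 2) / increment) + 1
  values <- minimum + (seq_len(n) - 1) * increment
  structure(list(parameter = parameter, minimum = minimum, maximum = maximum,
                 increment = increment, direction = direction,
                 values = values),
            class = "threshold_grid")
}

#' Default full-range threshold grids
#'
#' The clinical evaluation grids: CBV 1-10 ml/100g step 0.1; MTT 1-20 s
#' step 0.5; CBF 1-90 ml/100g/min step 1; Tmax 1-16 s step 0.5; CBV_rel
#' 0.05-3.5 step 0.05; MTT_rel 0.05-3 step 0.05; CBF_rel 0.05-3 step 0.05;
#' Tmax_rel 0.05-4 step 0.05.  TTP and TTP_rel (used by the ATS map sets,
#' which carry TTP instead of Tmax) reuse the Tmax grid bounds since the
#' units and physiological range coincide.
#'
#' @return Named list of [make_threshold_grid()] objects.
#' @export
default_threshold_grids <- function() {
  list(
    cbv      = make_threshold_grid("cbv", 1, 10, 0.1),
    mtt      = make_threshold_grid("mtt", 1, 20, 0.5),
    cbf      = make_threshold_grid("cbf", 1, 90, 1),
    tmax     = make_threshold_grid("tmax", 1, 16, 0.5),
    ttp      = make_threshold_grid("ttp", 1, 16, 0.5),
    cbv_rel  = make_threshold_grid("cbv_rel", 0.05, 3.5, 0.05),
    mtt_rel  = make_threshold_grid("mtt_rel", 0.05, 3, 0.05),
    cbf_rel  = make_threshold_grid("cbf_rel", 0.05, 3, 0.05),
    tmax_rel = make_threshold_grid("tmax_rel", 0.05, 4, 0.05),
    ttp_rel  = make_threshold_grid("ttp_rel", 0.05, 4, 0.05)
  )
}

#' Binarize a parametric map at a threshold
#'
#' Voxels are set to 1 where the map value exceeds the threshold
#' (`direction = "above"`), or falls below it (`"below"`), and to zero
#' otherwise; voxels outside the evaluation mask (or with undefined map
#' values) are always zero.
#'
#' @param map 3D numeric volume.
#' @param threshold Threshold in map units.
#' @param direction `"above"` or `"below"`.
#' @param eval_mask Optional logical array restricting the prediction.
#' @return Logical array of the map's shape.
#' @export
binarize <- function(map, threshold, direction = c("above", "below"),
                     eval_mask = NULL) {
  direction <- match.arg(direction)
  pred <- if (direction == "above") map > threshold else map < threshold
  pred[is.na(pred)] <- FALSE
  if (!is.null(eval_mask)) pred <- pred & eval_mask
  pred
}

#' Voxel-wise confusion counts
#'
#' Counts true/false positives and negatives of a binary prediction against
#' a reference mask over the evaluation mask, with sensitivity
#' `tp/(tp+fn)` and specificity `tn/(tn+fp)` (`NA` when the respective
#' denominator is empty, e.g. no reference voxels inside the mask).
#'
#' @param pred,ref Logical arrays of equal shape.
#' @param eval_mask Optional logical array; counts are restricted to it.
#' @return An object of class `ctp_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`.
#' @export
confusion <- function(pred, ref, eval_mask = NULL) {
  if (!all(dim2(pred) == dim2(ref))) .stop_invalid("'pred' and 'ref' shapes differ")
  if (is.null(eval_mask)) eval_mask <- rep(TRUE, length(pred))
  else if (!all(dim2(eval_mask) == dim2(pred))) .stop_invalid("'eval_mask' shape differs")
  p <- as.logical(pred)[as.logical(eval_mask)]
  r <- as.logical(ref)[as.logical(eval_mask)]
  counts_to_confusion(tp = sum(p & r), fp = sum(p & !r),
                      tn = sum(!p & !r), fn = sum(!p & r))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

counts_to_confusion <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec),
            class = "ctp_confusion")
}

#' Dice overlap coefficient
#'
#' `2|P intersect R| / (|P| + |R|)` over the evaluation mask.  When both
#' sets are empty the coefficient is undefined and `NA` is returned (such
#' cases are excluded from summaries rather than scored 0 or 1).
#'
#' @inheritParams confusion
#' @return Dimensionless overlap in `[0, 1]`, or `NA`.
#' @export
dice_coefficient <- function(pred, ref, eval_mask = NULL) {
  cc <- confusion(pred, ref, eval_mask)
  .dice_from_counts(cc$tp, cc$fp, cc$fn)
}

.dice_from_counts <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  ifelse(denom > 0, 2 * tp / denom, NA_real_)
}

#' Youden index
#'
#' `sensitivity + specificity - 1`, in `[-1, 1]`; `NA` when either term is
#' undefined.
#'
#' @param x A `ctp_confusion`, or a numeric sensitivity when `spec` is
#'   given.
#' @param spec Optional specificity.
#' @return Dimensionless index.
#' @export
youden_index <- function(x, spec = NULL) {
  if (inherits(x, "ctp_confusion")) return(x$sensitivity + x$specificity - 1)
  x + spec - 1
}

# threshold sweep on masked, finite value/label vectors
.sweep_counts <- function(values, labels, grid) {
  npos <- sum(labels)
  n <- length(values)
  vp <- values[labels]
  tab <- vapply(grid$values, function(t) {
    if (grid$direction == "above") {
      tp <- sum(vp > t); pp <- sum(values > t)
    } else {
      tp <- sum(vp < t); pp <- sum(values < t)
    }
    c(tp = tp, fp = pp - tp, tn = (n - pp) - (npos - tp), fn = npos - tp)
  }, numeric(4))
  data.frame(threshold = grid$values, t(tab))
}

# extract masked finite values/labels for one subject
.masked_values <- function(map, fiv, eval_mask) {
  keep <- as.logical(eval_mask) & is.finite(map)
  list(values = map[keep], labels = as.logical(fiv)[keep])
}

.annotate_sweep <- function(tab) {
  tab$sensitivity <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), NA_real_)
  tab$specificity <- ifelse(tab$tn + tab$fp > 0, tab$tn / (tab$tn + tab$fp), NA_real_)
  tab$fpr <- 1 - tab$specificity
  tab$dice <- .dice_from_counts(tab$tp, tab$fp, tab$fn)
  tab$youden <- tab$sensitivity + tab$specificity - 1
  tab
}

# sweep counts for one subject or summed over a list of subjects
.sweep_table <- function(map, grid, fiv, eval_mask, pooling) {
  if (is.list(map) && !is.null(dim(map[[1]]))) {
    stopifnot(is.list(fiv), is.list(eval_mask))
    tabs <- mapply(function(m, f, e) {
      mv <- .masked_values(m, f, e)
      .sweep_counts(mv$values, mv$labels, grid)
    }, map, fiv, eval_mask, SIMPLIFY = FALSE)
    if (identical(pooling, "pooled")) {
      tab <- tabs[[1]]
      for (i in seq_along(tabs)[-1])
        tab[, c("tp", "fp", "tn", "fn")] <-
          tab[, c("tp", "fp", "tn", "fn")] + tabs[[i]][, c("tp", "fp", "tn", "fn")]
      return(.annotate_sweep(tab))
    }
    return(lapply(tabs, .annotate_sweep))
  }
  mv <- .masked_values(map, fiv, eval_mask)
  .annotate_sweep(.sweep_counts(mv$values, mv$labels, grid))
}

#' Trapezoidal area under ROC points
#'
#' Points are sorted by false-positive rate (ties broken by sensitivity),
#' the anchors (0,0) and (1,1) are appended, and the area is accumulated by
#' the trapezoidal rule.
#'
#' @param fpr,sens Numeric vectors of ROC coordinates (NA pairs dropped).
#' @return Area in `[0, 1]`.
#' @export
trapezoid_auc <- function(fpr, sens) {
  ok <- is.finite(fpr) & is.finite(sens)
  x <- c(0, fpr[ok], 1)
  y <- c(0, sens[ok], 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Voxel-wise ROC curve over a threshold grid
#'
#' Builds one confusion per grid threshold; each threshold contributes one
#' point (1-specificity, sensitivity) of the ROC curve.  For a list of
#' subjects, `pooling = "pooled"` sums tp/fp/tn/fn across subjects before
#' computing rates (one cohort-level curve), whereas `pooling = "subject"`
#' returns one curve per subject.
#'
#' @param map 3D map volume, or a list of volumes (one per subject).
#' @param grid A [make_threshold_grid()] object.
#' @param fiv Reference FIV mask(s) on the same grid(s).
#' @param eval_mask Evaluation mask(s); `NULL` evaluates everywhere.
#' @param pooling `"pooled"` or `"subject"`.
#' @return A `ctp_roc` object: `parameter`, `table` (threshold, counts,
#'   sensitivity, specificity, fpr, dice, youden) and `auc`; or a list of
#'   them in subject mode.
#' @export
roc_curve <- function(map, grid, fiv, eval_mask = NULL,
                      pooling = c("pooled", "subject")) {
  pooling <- match.arg(pooling)
  if (!inherits(grid, "threshold_grid")) .stop_invalid("'grid' must be a 'threshold_grid'")
  if (is.null(eval_mask)) {
    eval_mask <- if (is.list(map)) lapply(map, function(m) array(TRUE, dim = dim(m)))
                 else array(TRUE, dim = dim(map))
  }
  tab <- .sweep_table(map, grid, fiv, eval_mask, pooling)
  if (is.data.frame(tab)) return(.roc_from_table(tab, grid$parameter))
  lapply(tab, .roc_from_table, parameter = grid$parameter)
}

.roc_from_table <- function(tab, parameter) {
  if (all(tab$tp + tab$fp == 0))
    warning("degenerate ROC: empty predictions at every threshold")
  auc <- trapezoid_auc(tab$fpr, tab$sensitivity)
  structure(list(parameter = parameter, table = tab, auc = auc),
            class = "ctp_roc")
}

#' @export
print.ctp_roc <- function(x, ...) {
  cat("ROC [", x$parameter, "]: ", nrow(x$table), " thresholds, AUC = ",
      round(x$auc, 3), "\n", sep = "")
  invisible(x)
}

#' Optimal threshold by Youden index or Dice coefficient
#'
#' Maximizes the criterion over the grid; thresholds with an undefined
#' criterion are skipped.  Ties are broken towards the smallest threshold
#' (the most sensitive prediction), deterministically.
#'
#' @inheritParams roc_curve
#' @param criterion `"dice"` or `"youden"`.
#' @return An `optimal_threshold` object: `criterion`, `threshold`,
#'   `score`.
#' @export
optimal_threshold <- function(map, grid, fiv, eval_mask = NULL,
                              criterion = c("dice", "youden"),
                              pooling = "pooled") {
  criterion <- match.arg(criterion)
  roc <- roc_curve(map, grid, fiv, eval_mask, pooling = "pooled")
  .optimum_from_table(roc$table, grid, criterion)
}

.optimum_from_table <- function(tab, grid, criterion) {
  score <- tab[[criterion]]
  if (all(is.na(score)))
    .stop_invalid("criterion '", criterion, "' undefined at every threshold")
  best <- max(score, na.rm = TRUE)
  hit <- which(!is.na(score) & score >= best - 1e-12)
  structure(list(criterion = criterion, threshold = tab$threshold[min(hit)],
                 score = best),
            class = "optimal_threshold")
}

#' Per-subject optimal-threshold distribution
#'
#' One optimum per subject; subjects whose reference mask is empty inside
#' the evaluation mask are excluded with a warning.
#'
#' @param maps,fivs,eval_masks Lists of per-subject volumes/masks.
#' @param grid A threshold grid.
#' @param criterion `"dice"` or `"youden"`.
#' @param subject_ids Optional character labels.
#' @return Data frame with `subject_id`, `threshold`, `score`.
#' @export
per_subject_optima <- function(maps, grid, fivs, eval_masks,
                               criterion = c("dice", "youden"),
                               subject_ids = NULL) {
  criterion <- match.arg(criterion)
  n <- length(maps)
  if (n < 1) .stop_invalid("need at least one subject")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  rows <- vector("list", n)
  dropped <- character(0)
  for (i in seq_len(n)) {
    ev <- eval_masks[[i]]
    if (!any(as.logical(fivs[[i]]) & as.logical(ev))) {
      dropped <- c(dropped, subject_ids[i])
      next
    }
    opt <- optimal_threshold(maps[[i]], grid, fivs[[i]], ev, criterion)
    rows[[i]] <- data.frame(subject_id = subject_ids[i],
                            threshold = opt$threshold, score = opt$score)
  }
  if (length(dropped))
    warning("excluded subjects with empty FIV inside the evaluation mask: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) .stop_invalid("no subject had reference voxels to evaluate")
  out
}

#' Vendor default ATS thresholding rule
#'
#' The factory rule: hypoperfused tissue where relative MTT exceeds 150%
#' of the contralateral value; ischemic core where additionally CBV falls
#' below 2 ml/100 g; penumbra is hypoperfused minus core.
#'
#' @param mtt_rel_cutoff Relative MTT cutoff (dimensionless), default 1.5.
#' @param cbv_cutoff Absolute CBV cutoff in ml/100 g, default 2.
#' @return An object of class `ats_default_rule`.
#' @export
ats_default_rule <- function(mtt_rel_cutoff = 1.5, cbv_cutoff = 2) {
  structure(list(mtt_rel_cutoff = mtt_rel_cutoff, cbv_cutoff = cbv_cutoff),
            class = "ats_default_rule")
}

#' Predict tissue compartments with the default ATS rule
#'
#' @param map_set A `ctp_map_set` with relative maps
#'   (see [compute_relative_maps()]).
#' @param rule An [ats_default_rule()].
#' @param target `"hypoperfused"`, `"core"` or `"penumbra"`.
#' @return Logical 3D prediction mask.
#' @export
ats_default_prediction <- function(map_set, rule = ats_default_rule(),
                                   target = c("hypoperfused", "core", "penumbra")) {
  target <- match.arg(target)
  if (is.null(map_set$mtt_rel) || is.null(map_set$cbv))
    .stop_invalid("map set lacks 'mtt_rel'/'cbv'; run compute_relative_maps() first")
  hypo <- map_set$mtt_rel > rule$mtt_rel_cutoff
  hypo[is.na(hypo)] <- FALSE
  if (target == "hypoperfused") return(hypo)
  core <- hypo & !is.na(map_set$cbv) & map_set$cbv < rule$cbv_cutoff
  if (target == "core") return(core)
  hypo & !core
}
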