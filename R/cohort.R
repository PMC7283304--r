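#' Volume of a binary mask in ml
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Volume in ml (`count * voxel volume / 1000`).
#' @examples
#' mask_volume(array(TRUE, c(10, 10, 10)), c(1, 1, 1))  # 1 ml
#' @export
mask_volume <- function(mask, voxel_size) {
  if (any(voxel_size <= 0)) .stop_invalid("'voxel_size' must be positive")
  sum(as.logical(mask)) * prod(voxel_size) / 1000
}

#' Pearson correlation of predicted volumes with FIV
#'
#' @param records Data frame with one row per subject, containing at least
#'   `fiv_ml` and the predicted-volume column.
#' @param predicted Name of the predicted-volume column.
#' @param group Optional group label (`"A"`/`"B"`) to subset on (requires a
#'   `group` column).
#' @return List with `r`, `n` and the two-sided `p` of the correlation
#'   test.  Zero variance in either vector yields `r = NA` with a warning.
#' @export
correlate_volumes <- function(records, predicted, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  x <- records[[predicted]]
  y <- records$fiv_ml
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) .stop_invalid("need at least 3 subjects with defined volumes")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a volume vector; correlation undefined")
    return(list(r = NA_real_, n = length(x), p = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Wilcoxon rank-sum comparison of a characteristic between groups
#'
#' Two-sided rank-sum test: exact enumeration when the combined sample size
#' is at most 20 and there are no ties, otherwise the normal approximation
#' with tie and continuity correction.  Identical constant samples give
#' `p = 1`.
#'
#' @param x,y Numeric samples for the two groups (both non-empty).
#' @param alpha Significance level for the `significant` flag.
#' @return List with `p`, `statistic` (the rank-sum W), and `significant`.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  if (length(x) < 1 || length(y) < 1) .stop_invalid("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(list(p = 1, statistic = NA_real_, significant = FALSE))
  ties <- any(duplicated(c(x, y)))
  use_exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  p <- min(wt$p.value, 1)
  list(p = p, statistic = unname(wt$statistic), significant = p < alpha)
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether two correlations sharing one variable (e.g. ATI-predicted
#' volume vs FIV against ATS-predicted volume vs FIV, both correlated with
#' the same FIV) differ, using the Williams-Steiger t statistic on
#' `n - 3` degrees of freedom.
#'
#' @param r12,r13 The two correlations being compared (each with the shared
#'   variable 1).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size.
#' @return List with `t`, `df`, two-sided `p`.
#' @export
compare_dependent_correlations <- function(r12, r13, r23, n) {
  if (n < 4) .stop_invalid("'n' must be at least 4")
  det <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * det * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  p <- 2 * pt(-abs(tstat), df = n - 3)
  list(t = tstat, df = n - 3, p = p)
}

#' Assemble the cohort report tables
#'
#' Collects the pipeline outputs into flat tables: per-subject volumes,
#' pooled AUCs per algorithm and parameter, optimal thresholds, volume
#' correlations and the group comparison.  Missing results appear as `NA`
#' cells rather than being dropped.
#'
#' @param result A `ctp_pipeline_result` from [run_pipeline()].
#' @return An object of class `ctp_report`: list of data frames
#'   (`subjects`, `auc`, `optimal_thresholds`, `correlations`,
#'   `group_comparison`).
#' @export
build_report <- function(result) {
  if (!inherits(result, "ctp_pipeline_result"))
    .stop_invalid("'result' must come from run_pipeline()")
  if (nrow(result$subjects) == 0) .stop_invalid("empty cohort: nothing to report")
  structure(list(subjects = result$subjects,
                 auc = result$auc,
                 optimal_thresholds = result$optimal_thresholds,
                 correlations = result$correlations,
                 group_comparison = result$group_comparison),
            class = "ctp_report")
}

#' Write report tables as CSV files
#'
#' Writing is deterministic: identical results give byte-identical files.
#'
#' @param report A `ctp_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "ctp_report")) .stop_invalid("'report' must be a 'ctp_report'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
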