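#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults (full-range
#' threshold grids, vendor ATS rule, 25 + 29 synthetic cohort) and checks
#' units and names.  Exactly one of the synthetic-phantom block
#' (`phantom`) and the real-data block (`subjects`) must be present; the
#' default configuration is fully synthetic.
#'
#' @param config `NULL` (all defaults), a path to a YAML file, or a list.
#' @return An object of class `ctp_run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) .stop_invalid("'config' must be a list or a YAML path")

  if (!is.null(config$phantom) && !is.null(config$subjects))
    .stop_invalid("set either 'phantom' (synthetic) or 'subjects' (real data), not both")
  mode <- if (is.null(config$subjects)) "phantom" else "real"

  phantom <- config$phantom
  ph <- list(n_a = 25L, n_b = 29L, noise_sd = 0.5,
             grid_shape = c(32L, 32L, 8L), voxel_size = c(2, 2, 5),
             n_timepoints = 30L, dt = 2)
  for (nm in names(phantom)) {
    if (!nm %in% names(ph)) .stop_invalid("unknown phantom field '", nm, "'")
    ph[[nm]] <- phantom[[nm]]
  }

  dc <- function(algorithm, overrides) {
    args <- c(list(algorithm = algorithm), overrides)
    do.call(deconv_config, args)
  }
  deconv <- list(ats = dc("ATS", config$deconv$ats),
                 ati = dc("ATI", config$deconv$ati))

  grids <- lapply(default_threshold_grids(), function(g)
    list(minimum = g$minimum, maximum = g$maximum,
         increment = g$increment, direction = g$direction))
  for (nm in names(config$grids)) {
    if (!nm %in% .CTP_PARAMETERS)
      .stop_invalid("unknown grid parameter '", nm, "'; valid names are: ",
                    paste(.CTP_PARAMETERS, collapse = ", "))
    g <- config$grids[[nm]]
    for (f in names(g)) grids[[nm]][[f]] <- g[[f]]
  }
  # constructing every grid validates min < max, increment > 0
  for (nm in names(grids))
    make_threshold_grid(nm, grids[[nm]]$minimum, grids[[nm]]$maximum,
                        grids[[nm]]$increment, grids[[nm]]$direction)

  pooling <- if (is.null(config$pooling)) "pooled" else
    match.arg(config$pooling, c("pooled", "subject"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  structure(list(mode = mode, phantom = ph, subjects = config$subjects,
                 deconv = deconv, grids = grids, pooling = pooling,
                 seed = seed,
                 write_nifti = isTRUE(config$write_nifti)),
            class = "ctp_run_config")
}

# parameters evaluated per algorithm (the ATS set carries TTP, the ATI set Tmax)
.algo_parameters <- function(algorithm) {
  if (algorithm == "ATS")
    c("cbf", "cbv", "mtt", "ttp", "cbf_rel", "cbv_rel", "mtt_rel", "ttp_rel")
  else
    c("cbf", "cbv", "mtt", "tmax", "cbf_rel", "cbv_rel", "mtt_rel", "tmax_rel")
}

# evaluate one subject: sweep count tables per algorithm/parameter plus
# volume bookkeeping; everything downstream is derived from these counts
.evaluate_subject <- function(subject, cfg, grids) {
  study <- subject$study
  fiv <- subject$truth$fiv_mask_true
  aif <- study$aif_true
  sets <- list(ATS = compute_relative_maps(compute_map_set(study, aif, cfg$deconv$ats)),
               ATI = compute_relative_maps(compute_map_set(study, aif, cfg$deconv$ati)))
  out <- list(subject_id = study$subject_id, group = study$group,
              fiv_ml = mask_volume(fiv, study$voxel_size),
              voxel_volume_ml = prod(study$voxel_size) / 1000,
              tables = list())
  for (algo in names(sets)) {
    set <- sets[[algo]]
    ev <- make_eval_mask(study, set)
    for (param in .algo_parameters(algo)) {
      g <- grids[[param]]
      tab <- .sweep_table(map_parameter(set, param), g, fiv, ev, "subject")
      out$tables[[paste(algo, param, sep = ".")]] <- tab
    }
    if (algo == "ATS") {
      out$ats_hypo_ml <- mask_volume(ats_default_prediction(set, target = "hypoperfused") & ev,
                                     study$voxel_size)
      out$ats_core_ml <- mask_volume(ats_default_prediction(set, target = "core") & ev,
                                     study$voxel_size)
    }
  }
  out
}

.sum_tables <- function(tabs) {
  tab <- tabs[[1]]
  cols <- c("tp", "fp", "tn", "fn")
  for (i in seq_along(tabs)[-1]) tab[, cols] <- tab[, cols] + tabs[[i]][, cols]
  .annotate_sweep(tab[, c("threshold", cols)])
}

# predicted voxel count at the grid threshold nearest to `thr`
.predicted_volume_at <- function(tab, thr, voxel_volume_ml) {
  i <- which.min(abs(tab$threshold - thr))
  (tab$tp[i] + tab$fp[i]) * voxel_volume_ml
}

#' Run the full experiment
#'
#' Orchestrates phantom generation (or real-data loading), ATS and ATI map
#' computation, threshold sweeps, pooled and per-subject optimal-threshold
#' selection, predicted-volume/FIV correlation and the group comparison,
#' and optionally writes the report tables plus a reproducibility manifest.
#'
#' Per-group pooled sweeps drive the AUC tables and the cohort-level
#' optimal thresholds of the group's headline parameter (Tmax for group A,
#' contralateral-relative CBF for group B).  Predicted volumes per subject
#' are taken at those pooled optima (Dice and Youden variants) for ATI and
#' from the vendor default rule for ATS (hypoperfused extent for group A,
#' core for group B).  Failures of individual subjects are logged and
#' skipped; the run aborts only if every subject fails.
#'
#' @param config Anything accepted by [validate_config()].
#' @param out_dir Optional output directory for CSV tables and
#'   `manifest.yaml`.
#' @param cohort Optional pre-built `ctp_cohort` (overrides the phantom
#'   block; used for planted-truth experiments).
#' @return An object of class `ctp_pipeline_result` with the report data
#'   frames (`subjects`, `auc`, `optimal_thresholds`, `correlations`,
#'   `group_comparison`), the pooled count tables and the normalized
#'   config.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, cohort = NULL) {
  cfg <- if (inherits(config, "ctp_run_config")) config else validate_config(config)
  grids <- lapply(names(cfg$grids), function(nm)
    make_threshold_grid(nm, cfg$grids[[nm]]$minimum, cfg$grids[[nm]]$maximum,
                        cfg$grids[[nm]]$increment, cfg$grids[[nm]]$direction))
  names(grids) <- names(cfg$grids)

  if (is.null(cohort)) {
    if (cfg$mode == "phantom") {
      base <- phantom_spec(grid_shape = cfg$phantom$grid_shape,
                           voxel_size = cfg$phantom$voxel_size,
                           n_timepoints = cfg$phantom$n_timepoints,
                           dt = cfg$phantom$dt,
                           noise_sd = cfg$phantom$noise_sd)
      cohort <- build_cohort(cfg$phantom$n_a, cfg$phantom$n_b,
                             base_spec = base, seed = cfg$seed)
    } else {
      cohort <- .load_real_cohort(cfg$subjects)
    }
  }

  evals <- list(); failures <- character(0)
  for (i in seq_along(cohort)) {
    res <- tryCatch(.evaluate_subject(cohort[[i]], cfg, grids),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(cohort[[i]]$study$subject_id, ": ",
                                     conditionMessage(res)))
    } else {
      evals[[length(evals) + 1]] <- res
    }
  }
  if (length(evals) == 0)
    .stop_invalid("all subjects failed: ", paste(failures, collapse = "; "))

  groups <- vapply(evals, `[[`, character(1), "group")
  table_names <- names(evals[[1]]$tables)

  # pooled tables and AUCs per group x algorithm x parameter
  pooled <- list(); auc_rows <- list()
  for (grp in sort(unique(groups))) {
    sel <- which(groups == grp)
    for (tn in table_names) {
      tab <- .sum_tables(lapply(evals[sel], function(e) e$tables[[tn]]))
      pooled[[paste(grp, tn, sep = ".")]] <- tab
      parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
      auc_rows[[length(auc_rows) + 1]] <- data.frame(
        group = grp, algorithm = parts[1], parameter = parts[2],
        auc = trapezoid_auc(tab$fpr, tab$sensitivity))
    }
  }
  auc <- do.call(rbind, auc_rows)

  # group-level optimal thresholds of the headline ATI parameters
  headline <- c(A = "tmax", B = "cbf_rel")
  opt_rows <- list()
  for (grp in intersect(names(headline), unique(groups))) {
    param <- headline[[grp]]
    tab <- pooled[[paste(grp, "ATI", param, sep = ".")]]
    for (crit in c("dice", "youden")) {
      opt <- .optimum_from_table(tab, grids[[param]], crit)
      opt_rows[[length(opt_rows) + 1]] <- data.frame(
        group = grp, algorithm = "ATI", parameter = param, criterion = crit,
        threshold = opt$threshold, score = opt$score)
    }
  }
  optimal_thresholds <- do.call(rbind, opt_rows)

  # per-subject volumes at the group's pooled optima
  subjects <- data.frame(
    subject_id = vapply(evals, `[[`, character(1), "subject_id"),
    group = groups,
    fiv_ml = vapply(evals, `[[`, numeric(1), "fiv_ml"),
    pred_ats_ml = vapply(evals, function(e)
      if (e$group == "A") e$ats_hypo_ml else e$ats_core_ml, numeric(1)))
  for (crit in c("dice", "youden")) {
    subjects[[paste0("pred_ati_", crit, "_ml")]] <- vapply(seq_along(evals),
      function(i) {
        grp <- groups[i]
        param <- headline[[grp]]
        if (is.null(param)) return(NA_real_)
        row <- optimal_thresholds[optimal_thresholds$group == grp &
                                    optimal_thresholds$criterion == crit, ]
        if (nrow(row) == 0) return(NA_real_)
        .predicted_volume_at(evals[[i]]$tables[[paste("ATI", param, sep = ".")]],
                             row$threshold[1], evals[[i]]$voxel_volume_ml)
      }, numeric(1))
  }

  # correlations with FIV, and ATI-vs-ATS dependent-correlation comparison
  cor_rows <- list()
  for (grp in sort(unique(groups))) {
    gsub <- subjects[subjects$group == grp, ]
    if (nrow(gsub) < 4) next
    r_ats <- correlate_volumes(gsub, "pred_ats_ml")$r
    for (crit in c("dice", "youden")) {
      col <- paste0("pred_ati_", crit, "_ml")
      r_ati <- correlate_volumes(gsub, col)$r
      p_cmp <- if (is.na(r_ati) || is.na(r_ats)) NA_real_ else
        compare_dependent_correlations(
          r_ati, r_ats, cor(gsub[[col]], gsub$pred_ats_ml), nrow(gsub))$p
      cor_rows[[length(cor_rows) + 1]] <- data.frame(
        group = grp, criterion = crit, r_ati = r_ati, r_ats = r_ats,
        p_vs_ats = p_cmp)
    }
  }
  correlations <- if (length(cor_rows)) do.call(rbind, cor_rows) else
    data.frame(group = character(0), criterion = character(0),
               r_ati = numeric(0), r_ats = numeric(0), p_vs_ats = numeric(0))

  fiv_a <- subjects$fiv_ml[subjects$group == "A"]
  fiv_b <- subjects$fiv_ml[subjects$group == "B"]
  group_comparison <- if (length(fiv_a) && length(fiv_b)) {
    cmp <- compare_groups(fiv_a, fiv_b)
    data.frame(characteristic = "fiv_ml",
               mean_a = mean(fiv_a), sd_a = sd(fiv_a),
               mean_b = mean(fiv_b), sd_b = sd(fiv_b), p = cmp$p)
  } else {
    data.frame(characteristic = "fiv_ml", mean_a = NA_real_, sd_a = NA_real_,
               mean_b = NA_real_, sd_b = NA_real_, p = NA_real_)
  }

  result <- structure(list(subjects = subjects, auc = auc,
                           optimal_thresholds = optimal_thresholds,
                           correlations = correlations,
                           group_comparison = group_comparison,
                           pooled = pooled, failures = failures,
                           config = cfg),
                      class = "ctp_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(build_report(result), out_dir)
    .write_manifest(cfg, out_dir, n_ok = length(evals), failures = failures)
  }
  result
}

.write_manifest <- function(cfg, out_dir, n_ok, failures) {
  plain <- list(mode = cfg$mode, phantom = cfg$phantom,
                deconv = lapply(cfg$deconv, unclass),
                grids = cfg$grids, pooling = cfg$pooling, seed = cfg$seed)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(plain, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("ctpfiv")),
                   subjects_completed = n_ok,
                   subjects_failed = length(failures),
                   failures = as.list(failures))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

# real mode: each entry names a pre-aligned 4D CTP NIfTI, a FIV mask NIfTI
# on the CTP grid, an AIF curve CSV (column 'concentration'), and the group
.load_real_cohort <- function(entries) {
  subjects <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    for (f in c("ctp", "fiv", "aif", "group"))
      if (is.null(e[[f]])) .stop_invalid("real-data subject ", i, " lacks '", f, "'")
    study <- read_ctp_study(e$ctp, group = e$group,
                            subject_id = if (is.null(e$id)) sprintf("sub-%03d", i) else e$id,
                            dt = e$dt)
    fiv <- read_mask(e$fiv)
    if (!all(dim(fiv) == dim(study$data)[1:3]))
      .stop_invalid("FIV mask of subject ", i, " is not on the CTP grid; resample it first")
    study$aif_true <- utils::read.csv(e$aif)$concentration
    truth <- structure(list(fiv_mask_true = fiv), class = "subject_truth")
    structure(list(study = study, truth = truth), class = "ctp_subject")
  })
  structure(subjects, class = "ctp_cohort",
            table = data.frame(subject_id = vapply(subjects, function(s)
              s$study$subject_id, character(1))))
}

#' @export
print.ctp_pipeline_result <- function(x, ...) {
  cat("CTP pipeline result:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "A"), "A /", sum(x$subjects$group == "B"), "B )\n")
  if (length(x$failures)) cat("  failed:", length(x$failures), "\n")
  cat("  pooled AUC rows:", nrow(x$auc), "\n")
  invisible(x)
}
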