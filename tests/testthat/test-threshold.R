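test_that("threshold grids are inclusive arithmetic sequences of the stated size", {
  expect_length(make_threshold_grid("tmax", 1, 16, 0.5)$values, 31)
  expect_length(make_threshold_grid("mtt", 1, 20, 0.5)$values, 39)
  expect_equal(make_threshold_grid("cbf", 1, 2, 1)$values, c(1, 2))

  # every default grid matches a seq() enumeration oracle
  for (g in default_threshold_grids()) {
    expect_equal(g$values, seq(g$minimum, g$maximum + g$increment / 4,
                               by = g$increment),
                 tolerance = 1e-12)
    expect_lte(max(g$values), g$maximum + g$increment / 2)
  }

  expect_error(make_threshold_grid("cbf", 2, 1, 0.5), "minimum < maximum")
  expect_error(make_threshold_grid("cbf", 1, 2, 0), "increment")
  expect_error(make_threshold_grid("tmaxx", 1, 2, 1))
})

test_that("lesion directions default to above for times and below for flow/volume", {
  expect_equal(make_threshold_grid("tmax", 1, 16, 0.5)$direction, "above")
  expect_equal(make_threshold_grid("mtt_rel", 0.05, 3, 0.05)$direction, "above")
  expect_equal(make_threshold_grid("cbf", 1, 90, 1)$direction, "below")
  expect_equal(make_threshold_grid("cbv_rel", 0.05, 3.5, 0.05)$direction, "below")
})

test_that("binarize applies the strict threshold rule inside the mask", {
  m <- array(c(2, 5, 7, 9), dim = c(2, 2, 1))   # column-major: [[2,7],[5,9]]
  expect_equal(binarize(m, 6, "above") + 0, array(c(0, 0, 1, 1), dim = c(2, 2, 1)))
  m2 <- array(c(0.3, 0.9), dim = c(1, 2, 1))
  expect_equal(binarize(m2, 0.6, "below") + 0, array(c(1, 0), dim = c(1, 2, 1)))
  expect_false(any(binarize(m, max(m), "above")))
  ev <- array(c(TRUE, FALSE, TRUE, FALSE), dim = c(2, 2, 1))
  expect_equal(binarize(m, 1, "above", ev), ev)
})

test_that("confusion counts match a hand-counted 10-voxel toy", {
  pred <- array(c(1, 1, 1, 0, 0, 0, 1, 0, 0, 0), dim = c(10, 1, 1)) > 0
  ref  <- array(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0), dim = c(10, 1, 1)) > 0
  cc <- confusion(pred, ref)
  expect_equal(cc$sensitivity, 0.5)      # 3 of 6 reference voxels hit
  expect_equal(cc$specificity, 0.75)     # 1 of 4 background voxels flagged
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 10)

  perfect <- confusion(ref, ref)
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(1, 1))
  inverted <- confusion(!ref, ref)
  expect_equal(c(inverted$sensitivity, inverted$specificity), c(0, 0))
  expect_error(confusion(pred, ref[1:5, , , drop = FALSE]), "shapes differ")
})

test_that("Dice and Youden follow their closed forms", {
  a <- array(c(rep(TRUE, 4), rep(FALSE, 6)), dim = c(10, 1, 1))
  b <- array(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
             dim = c(10, 1, 1))
  expect_equal(dice_coefficient(a, b), 2 * 3 / (4 + 6))
  expect_equal(dice_coefficient(a, a), 1)
  disj <- array(c(rep(FALSE, 4), rep(TRUE, 6)), dim = c(10, 1, 1))
  expect_equal(dice_coefficient(a, disj), 0)
  none <- array(FALSE, dim = c(10, 1, 1))
  expect_true(is.na(dice_coefficient(none, none)))   # undefined, not 0 or 1

  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.3, 0.7), 0)            # chance: sens = 1 - spec
  expect_equal(youden_index(0.8, 0.7), 0.5)
})

test_that("ROC separates a perfect map and stays at chance for noise", {
  set.seed(7)
  dims <- c(12, 12, 2)
  fiv <- array(FALSE, dim = dims)
  fiv[4:9, 4:9, ] <- TRUE
  g <- make_threshold_grid("tmax", 1, 16, 0.5)

  sep <- array(2, dim = dims)
  sep[fiv] <- 10                              # one threshold separates exactly
  roc <- roc_curve(sep, g, fiv)
  expect_equal(roc$auc, 1)
  expect_equal(nrow(roc$table), 31)

  # i.i.d. noise independent of the reference: AUC ~ 0.5
  aucs <- vapply(1:10, function(i) {
    set.seed(i)
    noise <- array(runif(prod(dims), 1, 16), dim = dims)
    roc_curve(noise, g, fiv)$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("trapezoidal AUC matches the polygon-area oracle on small toys", {
  set.seed(11)
  for (i in 1:20) {
    fpr <- sort(runif(3))
    sens <- sort(runif(3))
    expect_equal(trapezoid_auc(fpr, sens), oracle_polygon_auc(fpr, sens),
                 tolerance = 1e-12)
  }
})

test_that("predicted volume is monotone along the threshold grid", {
  set.seed(3)
  m <- array(runif(500, 0, 16), dim = c(10, 10, 5))
  fiv <- array(runif(500) > 0.7, dim = c(10, 10, 5))
  for (dir in c("above", "below")) {
    g <- make_threshold_grid("tmax", 1, 16, 0.5, direction = dir)
    tab <- roc_curve(m, g, fiv)$table
    counts <- tab$tp + tab$fp
    if (dir == "above") expect_true(all(diff(counts) <= 0))
    else expect_true(all(diff(counts) >= 0))
    # sensitivity and fpr are monotone along the grid as well
    expect_true(all(diff(tab$sensitivity) <= 1e-12) ||
                all(diff(tab$sensitivity) >= -1e-12))
  }
})

test_that("AUC of a separable noiseless map is invariant under grid refinement", {
  dims <- c(12, 12, 2)
  fiv <- array(FALSE, dim = dims); fiv[4:9, 4:9, ] <- TRUE
  sep <- array(2, dim = dims); sep[fiv] <- 10
  coarse <- roc_curve(sep, make_threshold_grid("tmax", 1, 16, 1), fiv)$auc
  fine <- roc_curve(sep, make_threshold_grid("tmax", 1, 16, 0.25), fiv)$auc
  expect_equal(coarse, fine)
})

test_that("optimal thresholds maximize the criterion with smallest-threshold ties", {
  dims <- c(12, 12, 2)
  fiv <- array(FALSE, dim = dims); fiv[4:9, 4:9, ] <- TRUE
  sep <- array(2, dim = dims); sep[fiv] <- 10
  g <- make_threshold_grid("tmax", 1, 16, 0.5)
  for (crit in c("dice", "youden")) {
    opt <- optimal_threshold(sep, g, fiv, criterion = crit)
    expect_equal(opt$score, 1)
    # every threshold in [2, 10) separates; ties break to the smallest
    expect_equal(opt$threshold, 2)
  }

  # grid argmax tracks the dense-grid argmax within one increment
  set.seed(5)
  vals <- array(runif(prod(dims), 0, 16), dim = dims)
  fiv2 <- vals > 9        # unimodal criterion in the threshold
  coarse <- optimal_threshold(vals, make_threshold_grid("tmax", 1, 16, 0.5),
                              fiv2, criterion = "dice")
  dense <- optimal_threshold(vals, make_threshold_grid("tmax", 1, 16, 0.01),
                             fiv2, criterion = "dice")
  expect_lte(abs(coarse$threshold - dense$threshold), 0.5)
})

test_that("pooled ROC sums counts across subjects before computing rates", {
  set.seed(9)
  dims <- c(8, 8, 2)
  maps <- lapply(1:3, function(i) array(runif(prod(dims), 0, 16), dim = dims))
  fivs <- lapply(1:3, function(i) array(runif(prod(dims)) > 0.6, dim = dims))
  evs <- lapply(1:3, function(i) array(TRUE, dim = dims))
  g <- make_threshold_grid("tmax", 1, 16, 0.5)
  pooled <- roc_curve(maps, g, fivs, evs, pooling = "pooled")
  per <- roc_curve(maps, g, fivs, evs, pooling = "subject")
  expect_length(per, 3)
  manual_tp <- Reduce(`+`, lapply(per, function(r) r$table$tp))
  expect_equal(pooled$table$tp, manual_tp)
  expect_equal(pooled$table$tp + pooled$table$fn,
               rep(sum(vapply(fivs, sum, numeric(1))), 31))
})

test_that("per-subject optima recover planted cutoffs and drop empty subjects", {
  dims <- c(10, 10, 2)
  mk <- function(cut) {
    # background ramps up to just below the cutoff; lesion sits at it
    m <- array(seq(0.5, cut - 0.25, length.out = prod(dims)), dim = dims)
    f <- array(FALSE, dim = dims)
    f[6:9, 6:9, ] <- TRUE
    m[f] <- cut + 0.1
    list(m = m, f = f)
  }
  s1 <- mk(4); s2 <- mk(8)
  g <- make_threshold_grid("tmax", 1, 16, 0.5)
  out <- per_subject_optima(list(s1$m, s2$m), g, list(s1$f, s2$f),
                            list(array(TRUE, dims), array(TRUE, dims)), "dice")
  expect_equal(nrow(out), 2)
  expect_lte(abs(out$threshold[1] - 4), 0.5)
  expect_lte(abs(out$threshold[2] - 8), 0.5)

  # identical subjects: zero spread
  out2 <- per_subject_optima(list(s1$m, s1$m), g, list(s1$f, s1$f),
                             list(array(TRUE, dims), array(TRUE, dims)), "dice")
  expect_equal(sd(out2$threshold), 0)

  # a subject with no reference voxels is excluded with a warning
  empty <- array(FALSE, dims)
  expect_warning(
    out3 <- per_subject_optima(list(s1$m, s2$m), g, list(s1$f, empty),
                               list(array(TRUE, dims), array(TRUE, dims)), "dice"),
    "excluded")
  expect_equal(nrow(out3), 1)
})

test_that("the vendor default ATS rule classifies the three canonical voxels", {
  mk_set <- function(mtt_rel, cbv) {
    structure(list(algorithm = "ATS",
                   mtt_rel = array(mtt_rel, dim = c(1, 1, 1)),
                   cbv = array(cbv, dim = c(1, 1, 1)),
                   valid_mask = array(TRUE, dim = c(1, 1, 1))),
              class = "ctp_map_set")
  }
  expect_true(ats_default_prediction(mk_set(1.6, 1.5), target = "core")[1])
  expect_true(ats_default_prediction(mk_set(1.6, 3.0), target = "penumbra")[1])
  expect_false(ats_default_prediction(mk_set(1.6, 3.0), target = "core")[1])
  expect_false(ats_default_prediction(mk_set(1.2, 1.5), target = "hypoperfused")[1])
  # hypoperfused = core + penumbra (volume conservation of the rule)
  s <- build_subject(small_spec(noise_sd = 0.3), "A", seed = 4)
  ms <- compute_relative_maps(compute_map_set(s$study, s$study$aif_true,
                                              deconv_config("ATS")))
  hypo <- ats_default_prediction(ms, target = "hypoperfused")
  core <- ats_default_prediction(ms, target = "core")
  pen <- ats_default_prediction(ms, target = "penumbra")
  expect_equal(sum(hypo), sum(core) + sum(pen))
  expect_false(any(core & pen))
})

test_that("our grid ROC agrees with an independent continuous-ROC implementation", {
  set.seed(21)
  vals <- runif(400, 0, 10)
  labels <- runif(400) < plogis(vals - 5)       # graded association
  m <- array(vals, dim = c(400, 1, 1))
  f <- array(labels, dim = c(400, 1, 1))
  # threshold at every observed value: the grid ROC equals the classical
  # continuous ROC of the marker
  g <- make_threshold_grid("tmax", min(vals) - 1e-6, max(vals) + 1e-6,
                           (max(vals) - min(vals) + 2e-6) / 2000,
                           direction = "above")
  ours <- roc_curve(m, g, f)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, vals, direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 2e-3)
})
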