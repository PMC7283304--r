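test_that("gamma-variate AIF is zero before arrival, peaks at alpha*beta, scales linearly", {
  # no signal before bolus arrival
  a <- aif_spec(amplitude = 5, t0 = 8)
  expect_equal(evaluate_aif(a, c(0, 2, 4, 6, 8)), rep(0, 5))

  # dense-grid search locates the analytic peak t = alpha * beta
  a2 <- aif_spec(amplitude = 1, t0 = 0, alpha = 3, beta = 1.5)
  tt <- seq(0, 30, by = 0.001)
  v <- evaluate_aif(a2, tt)
  expect_equal(tt[which.max(v)], 3 * 1.5, tolerance = 1e-3)
  expect_true(all(is.finite(v)) && all(v >= 0))

  # linearity in amplitude
  a3 <- aif_spec(amplitude = 2, t0 = 0, alpha = 3, beta = 1.5)
  expect_equal(evaluate_aif(a3, tt), 2 * v)
})

test_that("invalid AIF specifications are rejected", {
  expect_error(aif_spec(amplitude = -1), "amplitude")
  expect_error(aif_spec(beta = 0), "beta")
  expect_error(aif_spec(alpha = 0), "alpha")
  expect_error(aif_spec(t0 = -1), "t0")
  expect_error(evaluate_aif(aif_spec(), c(-2, 0, 2)), "non-negative")
  expect_error(evaluate_aif(aif_spec(), c(0, 1, 3)), "uniformly spaced")
})

test_that("tissue curves follow the indicator-dilution convolution model", {
  dt <- 2
  times <- default_times()
  aif <- evaluate_aif(aif_spec(), times)

  # zero flow gives a zero curve
  expect_equal(simulate_tissue_curve(aif, 0, 4, 0, dt), numeric(30))

  # a 4 s delay at dt = 2 is an exact 2-sample right shift
  c0 <- simulate_tissue_curve(aif, 60, 4, 0, dt)
  c4 <- simulate_tissue_curve(aif, 60, 4, 4, dt)
  expect_equal(c4[3:30], c0[1:28], tolerance = 1e-12)
  expect_equal(c4[1:2], c(0, 0))

  expect_error(simulate_tissue_curve(aif, 60, 0, 0, dt), "mtt")
  expect_error(simulate_tissue_curve(aif, 60, -2, 0, dt), "mtt")
})

test_that("coarse simulation matches a dense-grid convolution oracle", {
  # boxcar AIF and both residue families against dt = 0.01 numerical
  # convolution; the left-Riemann error is bounded by the one-cell mass at
  # the discontinuity, dt * max(aif) * max(k)
  dt <- 2
  times <- default_times()
  aifc <- function(t) ifelse(t >= 4 & t < 12, 10, 0)
  aif <- aifc(times)
  fd <- 0.01
  ft <- seq(0, 60, by = fd)
  fa <- aifc(ft)
  for (res in c("exponential", "boxcar")) {
    cur <- simulate_tissue_curve(aif, 60, 4, 0, dt, residue = res)
    fr <- if (res == "exponential") (60 / 6000) * exp(-ft / 4) else
      (60 / 6000) * as.numeric(ft < 4)
    dense <- fd * convolve(fa, rev(fr), type = "open")[seq_along(ft)]
    oracle <- dense[match(times, round(ft, 10))]
    bound <- dt * max(aif) * (60 / 6000)
    expect_lt(max(abs(cur - oracle)), bound + 1e-9)
  }
})

test_that("tissue-curve area obeys the central volume principle on long windows", {
  # fine temporal sampling, long window: area ratio -> CBV / 100
  dt <- 0.1
  times <- (0:1999) * dt
  aif <- evaluate_aif(aif_spec(), times)
  cur <- simulate_tissue_curve(aif, 60, 4, 0, dt)
  cbv_true <- 60 * 4 / 60
  expect_equal(sum(cur) / sum(aif), cbv_true / 100, tolerance = 0.02)
})

test_that("noiseless curves are non-negative and peak after the AIF peak plus delay", {
  times <- default_times()
  aif <- evaluate_aif(aif_spec(), times)
  for (d in c(0, 2, 6)) {
    cur <- simulate_tissue_curve(aif, 40, 6, d, 2)
    expect_true(all(cur >= -1e-12))
    expect_gte(times[which.max(cur)], times[which.max(aif)] + d)
  }
})

test_that("build_subject is deterministic and encodes the group-wise FIV rule", {
  spec <- small_spec(noise_sd = 0.4)
  s1 <- build_subject(spec, "A", seed = 7)
  s2 <- build_subject(spec, "A", seed = 7)
  expect_identical(s1$study$data, s2$study$data)
  expect_identical(s1$truth$fiv_mask_true, s2$truth$fiv_mask_true)

  lab <- s1$truth$region_label_map
  # group A: FIV = core + penumbra; group B: core only
  expect_equal(sum(s1$truth$fiv_mask_true),
               sum(lab == "core") + sum(lab == "penumbra"))
  sB <- build_subject(spec, "B", seed = 7)
  expect_equal(sum(sB$truth$fiv_mask_true), sum(lab == "core"))
  expect_identical(sB$truth$region_label_map, lab)
})

test_that("an all-normal noiseless phantom has identical curves everywhere", {
  spec <- phantom_spec(grid_shape = c(8L, 8L, 4L), noise_sd = 0,
                       regions = list(region_spec("normal", 60, 4, 0)))
  s <- build_subject(spec, "A", seed = 1)
  mat <- matrix(s$study$data, prod(dim(s$study$data)[1:3]))
  expect_equal(max(apply(mat, 2, function(x) diff(range(x)))), 0)
})

test_that("phantom truth satisfies the central volume principle exactly", {
  s <- build_subject(small_spec(), "A", seed = 1)
  expect_equal(s$truth$cbv, s$truth$cbf * s$truth$mtt / 60, tolerance = 1e-12)
})

test_that("phantom truth is mirror-symmetric outside the lesion", {
  s <- build_subject(small_spec(), "A", seed = 1)
  cbf <- s$truth$cbf
  nx <- dim(cbf)[1]
  mirrored <- cbf[nx:1, , ]
  lesion <- s$truth$region_label_map != "normal"
  outside <- !(lesion | lesion[nx:1, , ])
  expect_equal(cbf[outside], mirrored[outside])
})

test_that("midline-crossing or out-of-grid lesions are rejected", {
  bad <- phantom_spec(grid_shape = c(16L, 16L, 4L), regions = list(
    region_spec("normal", 60, 4, 0),
    region_spec("core", 8, 10, 6, center = c(8, 8, 2), radii = c(3, 3, 1.5))))
  expect_error(build_subject(bad, "A"), "midline")
  expect_error(phantom_spec(grid_shape = c(15L, 16L, 4L)), "even")
})

test_that("region orderings and invalid specs are enforced", {
  expect_error(region_spec("core", cbf = -1, mtt = 10, delay = 6), "cbf")
  expect_error(region_spec("core", cbf = 8, mtt = 10, delay = 6), "center")
  # core CBF must stay below penumbra below normal
  expect_error(phantom_spec(grid_shape = c(16L, 16L, 4L), regions = list(
    region_spec("normal", 60, 4, 0),
    region_spec("penumbra", 10, 7, 3, center = c(12, 8, 2), radii = c(3, 3, 1.5)),
    region_spec("core", 30, 10, 6, center = c(12, 8, 2), radii = c(2, 2, 1)))),
    "core < penumbra < normal")
  expect_equal(region_cbv(region_spec("normal", 60, 4, 0)), 4)
})

test_that("build_cohort draws per-subject parameters and respects group sizes", {
  coh <- build_cohort(2, 3, base_spec = small_spec(noise_sd = 0.2), seed = 5)
  expect_length(coh, 5)
  tab <- attr(coh, "table")
  expect_equal(as.vector(table(tab$group)[c("A", "B")]), c(2, 3))
  expect_equal(tab$subject_id, sprintf("sub-%03d", 1:5))

  # degenerate ranges pin every subject to the same parameters
  samp <- cohort_sampler(core_cbf = c(8, 8), core_mtt = c(10, 10),
                         core_delay = c(6, 6), pen_cbf = c(25, 25),
                         pen_mtt = c(7, 7), pen_delay = c(3, 3),
                         size_scale = c(1, 1))
  coh2 <- build_cohort(1, 2, sampler = samp, base_spec = small_spec(noise_sd = 0.2),
                       seed = 5)
  tab2 <- attr(coh2, "table")
  expect_equal(var(tab2$core_cbf), 0)
  expect_equal(var(tab2$pen_delay), 0)

  expect_error(cohort_sampler(core_cbf = c(12, 6)), "core_cbf")
  expect_error(build_cohort(0, 3), "n_a")
})

test_that("the planted-delay cohort separates FIV from background at 6 s", {
  coh <- planted_delay_cohort(4, noise_sd = 0, seed = 1)
  tab <- attr(coh, "table")
  expect_equal(max(tab$pen_delay), 5.5)
  expect_equal(min(tab$core_delay), 6)
  for (s in coh) {
    expect_equal(s$study$group, "B")
    # FIV is exactly the set of voxels with true delay >= 6 s
    expect_identical(s$truth$fiv_mask_true,
                     array(s$truth$delay >= 6, dim = dim(s$truth$delay)))
  }
})
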