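test_that("cortical patches are deterministic with configurable ROI sizes", {
  p <- make_cortical_patch(list(A1 = 500), rng_seed = 1)
  expect_length(p$rois$A1$curvature, 500L)
  expect_true(all(is.finite(p$rois$A1$curvature)))
  expect_true(all(p$rois$A1$inner_area > 0 & p$rois$A1$outer_area > 0))
  p2 <- make_cortical_patch(list(A1 = 500), rng_seed = 1)
  expect_identical(p$rois, p2$rois)
  expect_error(make_cortical_patch(list(A1 = 0)), "at least one vertex")
  # visual ROIs carry a centre-to-periphery eccentricity map
  pv <- make_cortical_patch(list(V1 = 100), rng_seed = 2)
  expect_true(all(pv$rois$V1$eccentricity >= 0 & pv$rois$V1$eccentricity <= 1))
})

test_that("zero correlation length gives a spatially white curvature field", {
  lag1 <- vapply(1:40, function(seed) {
    p <- make_cortical_patch(list(A1 = 400), corr_length = 0, rng_seed = seed)
    m <- matrix(p$rois$A1$curvature, p$rois$A1$nx, p$rois$A1$ny)
    stats::cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  }, numeric(1))
  expect_lt(abs(mean(lag1)), 0.02)
  # and a positive correlation length gives positive lag-1 autocorrelation
  p <- make_cortical_patch(list(A1 = 400), corr_length = 2, rng_seed = 1)
  m <- matrix(p$rois$A1$curvature, p$rois$A1$nx, p$rois$A1$ny)
  expect_gt(stats::cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ])), 0.5)
})

test_that("simulated datasets satisfy the 72-beta labelling invariants", {
  ds <- noiseless_dataset()
  expect_true(validate_vertex_beta_dataset(ds))
  expect_equal(dim(ds$betas)[3], 72L)
  expect_equal(nrow(ds$labels), 72L)
  expect_true(all(table(ds$labels$condition) == 12))
  expect_true(all(table(ds$labels$run) == 18))
  expect_equal(unique(ds$labels$day[ds$labels$run <= 2]), 1)
})

test_that("with zero noise and no effects, stimulation betas equal gain times base", {
  tr <- noiseless_truth()
  ds <- noiseless_dataset()
  g <- tr$depth_gain
  a1 <- which(ds$roi == "A1")
  # A blocks under visual attention: pure gain x base response
  idx <- which(ds$labels$condition == "A_AttV")
  for (d in 1:6) {
    expect_equal(unique(round(as.vector(ds$betas[a1, d, idx]), 12)),
                 round(g[d] * tr$activation_mean, 12))
  }
  # fixation-referenced V blocks in auditory cortex carry only deactivation
  idx_v <- which(ds$labels$condition == "V_AttV")
  expect_equal(unique(round(as.vector(ds$betas[a1, , idx_v]), 12)), -1)
})

test_that("the planted deactivation shape is recovered exactly at zero noise", {
  ds <- noiseless_dataset()
  sh_aud <- roi_contrast_shapes(ds, "A1", "V-Fix")$shapes
  expect_equal(mean(sh_aud$C), -1, tolerance = 1e-12)
  expect_equal(mean(sh_aud$L), 0, tolerance = 1e-12)
  sh_vis <- roi_contrast_shapes(ds, "V1", "A-Fix")$shapes
  expect_equal(mean(sh_vis$C), -1, tolerance = 1e-12)
  expect_equal(mean(sh_vis$L), -0.2, tolerance = 1e-12)
  sh_mod <- roi_contrast_shapes(ds, "A1", "AV-A")$shapes
  expect_equal(mean(sh_mod$C), 0.3, tolerance = 1e-12)
  expect_equal(mean(sh_mod$L), 0, tolerance = 1e-12)
})

test_that("noisy recovery of the planted deactivation constant is unbiased", {
  tr <- ground_truth(subject_sd_C = 0, subject_sd_L = 0, deact_patch_sd = 0)
  patch <- make_cortical_patch(list(A1 = 60, PT = 40, V1 = 60, V23 = 40),
                               rng_seed = 3)
  d <- default_design()
  Cs <- vapply(1:60, function(seed) {
    ds <- simulate_vertex_betas(patch, tr, d, 1, rng_seed = seed)[[1]]
    mean(roi_contrast_shapes(ds, "A1", "V-Fix")$shapes$C)
  }, numeric(1))
  expect_lt(abs(mean(Cs) - (-1)), 4 * stats::sd(Cs) / sqrt(length(Cs)) + 0.02)
})

test_that("deactivation and modulation fields correlate at the target rho", {
  d <- default_design()
  patch <- make_cortical_patch(list(A1 = 2000, PT = 10, V1 = 10, V23 = 10),
                               rng_seed = 4)
  tr <- ground_truth(rho_deact_mod = 0.8, noise_sd = 0)
  rhos <- vapply(1:30, function(seed) {
    ds <- simulate_vertex_betas(patch, tr, d, 1, rng_seed = seed)[[1]]
    f <- ds$truth_fields$A1
    stats::cor(f$deact_C, f$mod_C, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.8), 0.05)
})

test_that("attention preserves the pattern while crossmodal input alters it", {
  tr <- ground_truth(noise_sd = 0)
  ds <- simulate_vertex_betas(small_patch(), tr, default_design(), 1,
                              rng_seed = 9)[[1]]
  sim <- pattern_similarity(ds, "A1")
  # multiplicative gain alone (A pair) leaves the pattern rank-identical
  expect_equal(sim$rho$attention[1], 1, tolerance = 1e-12)
  # every attention pair is more similar than any crossmodal pair
  expect_gt(min(unlist(sim$rho$attention)), max(unlist(sim$rho$stimulus)))
  expect_gt(sim$contrast, 0)
})

test_that("voxel time series reproduce the design prediction and AR(1) noise", {
  d <- default_design()
  dm <- build_design_matrix(d, run = 1)
  expect_equal(dm$n_vols, 302L)
  withr::with_seed(1, b <- matrix(rnorm(length(dm$task_cols)), ncol = 1))
  noiseless <- simulate_voxel_timeseries(d, b, ar1_rho = 0, noise_sd = 0,
                                         dm = dm)
  expect_equal(noiseless$series,
               dm$X[, dm$task_cols] %*% b, tolerance = 1e-12)
  # pure AR(1) noise: sample lag-1 autocorrelation near rho
  ac <- vapply(1:20, function(seed) {
    sim <- simulate_voxel_timeseries(d, matrix(0, length(dm$task_cols), 1),
                                     ar1_rho = 0.4, noise_sd = 1,
                                     rng_seed = seed, dm = dm)
    x <- sim$series[, 1]
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(abs(mean(ac) - 0.4), 0.05)
  expect_error(simulate_voxel_timeseries(d, b, ar1_rho = 1), "ar1_rho")
})

test_that("datasets round-trip to plain-text tables", {
  ds <- noiseless_dataset()
  dir <- withr::local_tempdir()
  write_vertex_betas(ds, dir)
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  expect_equal(nrow(lab), 72L)
  m <- as.matrix(utils::read.delim(file.path(dir, "betas_depth1.tsv"),
                                   header = FALSE))
  expect_equal(dim(m), c(dim(ds$betas)[1], 72L))
  expect_equal(unname(m[1, 1]), ds$betas[1, 1, 1], tolerance = 1e-6)
})
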