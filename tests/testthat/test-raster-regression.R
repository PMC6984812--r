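test_that("binning partitions ranked vertices into near-equal contiguous bins", {
  withr::with_seed(1, s <- rnorm(103))
  prof <- matrix(rnorm(103 * 6), 103, 6)
  r <- sort_and_bin(s, prof, 10)
  expect_equal(sum(r$bin_sizes), 103L)
  expect_true(max(r$bin_sizes) - min(r$bin_sizes) <= 1)
  expect_equal(sort(unique(r$bin_of_vertex)), 1:10)
  expect_true(all(table(r$bin_of_vertex) == r$bin_sizes))
  expect_true(all(diff(r$bin_mean_sort) > 0))
  # B = vertex count: singleton bins in sorted order
  r1 <- sort_and_bin(s, prof, 103)
  expect_equal(r1$bin_mean_sort, sort(s))
  expect_equal(r1$profiles, prof[order(s, seq_along(s)), ])
  # direct enumeration: sort value = 0..99, 10 bins
  r2 <- sort_and_bin(0:99, matrix(0:99, ncol = 1), 10)
  expect_equal(r2$bin_mean_sort, 4.5 + 10 * (0:9))
  expect_error(sort_and_bin(1:5, matrix(0, 5, 1), 6), "more bins")
})

test_that("tied sort values bin stably by vertex index", {
  prof <- matrix(1:8, ncol = 1)
  r <- sort_and_bin(rep(0, 8), prof, 4)
  expect_equal(as.vector(r$profiles), c(1.5, 3.5, 5.5, 7.5))
  expect_equal(mean(r$profiles), mean(prof))
})

test_that("display smoothing preserves constants and matches the kernel oracle", {
  m <- matrix(rnorm(200 * 6), 200, 6)
  expect_equal(smooth_raster(m, 0), m)
  const <- matrix(3, 50, 2)
  expect_equal(smooth_raster(const, 0.2), const)
  # impulse response equals the truncated renormalized Gaussian kernel
  B <- 101L
  imp <- matrix(0, B, 1); imp[51, 1] <- 1
  fr <- 0.2
  sm <- smooth_raster(imp, fr)
  sigma <- fr * B / (2 * sqrt(2 * log(2)))
  rr <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-rr, rr), sd = sigma); k <- k / sum(k)
  # compare where the kernel window lies fully inside the raster (edges are
  # renormalized by design)
  centre <- (rr + 1):(B - rr)
  expect_equal(sm[centre, 1], k[51 - centre + rr + 1], tolerance = 1e-12)
  expect_error(smooth_raster(m, -0.1), "fwhm")
})

test_that("the day-split estimator recovers a planted cross-contrast slope", {
  slopes <- vapply(1:20, function(seed) {
    ds <- planted_raster_dataset(120, slope = 0.5, rng_seed = seed)
    crossval_shape_regression(ds, "A1", "V-Fix", "AV-A", shape = "C",
                              B = 40, compute_rasters = FALSE)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})

test_that("sorting noise against itself inflates the slope; the day split removes it", {
  # pure-noise dataset, contrast sorted against itself
  biased <- numeric(15); unbiased <- numeric(15)
  for (seed in 1:15) {
    ds <- planted_raster_dataset(100, slope = 0, noise_sd = 1, field_sd = 0,
                                 resid_sd = 0, rng_seed = seed)
    biased[seed] <- crossval_shape_regression(
      ds, "A1", "V-Fix", "V-Fix", shape = "C", B = 50, day_split = FALSE,
      compute_rasters = FALSE)$slope
    unbiased[seed] <- crossval_shape_regression(
      ds, "A1", "V-Fix", "V-Fix", shape = "C", B = 50,
      compute_rasters = FALSE)$slope
  }
  expect_gt(mean(biased), 0.9)          # selection bias: y regressed on itself
  expect_lt(abs(mean(unbiased)), 3 * stats::sd(unbiased) / sqrt(15) + 0.02)
})

test_that("binned and unbinned regressions agree when B equals the vertex count", {
  ds <- planted_raster_dataset(80, slope = 0.4, rng_seed = 3)
  full <- crossval_shape_regression(ds, "A1", "V-Fix", "AV-A", shape = "C",
                                    B = 80, compute_rasters = FALSE)
  # unbinned oracle computed directly from the per-vertex day-split shapes
  lab <- ds$labels
  slope_fold <- function(sort_runs, pred_runs) {
    s <- fit_laminar_glm(vertex_contrast_profiles(ds, "A1", "V-Fix",
                                                  runs = sort_runs))$C
    p <- fit_laminar_glm(vertex_contrast_profiles(ds, "A1", "AV-A",
                                                  runs = pred_runs))$C
    sx <- s - mean(s)
    sum(sx * p) / sum(sx^2)
  }
  oracle <- mean(c(slope_fold(1:2, 3:4), slope_fold(3:4, 1:2)))
  expect_equal(full$slope, oracle, tolerance = 1e-10)
})

test_that("group slope inference defaults bins to the smallest ROI count", {
  dss <- lapply(1:4, function(s) {
    planted_raster_dataset(60 + s, slope = 0.5, rng_seed = s, subject = s)
  })
  gr <- group_raster_slopes(dss, "A1", "V-Fix", "AV-A", shape = "C")
  expect_equal(gr$B, 61L)
  expect_length(gr$slopes, 4L)
  expect_true(is.finite(gr$t) && gr$p <= 1)
  expect_gt(mean(gr$slopes), 0.3)
})

test_that("raster display objects carry the binned 6-depth profiles", {
  ds <- planted_raster_dataset(90, slope = 0.5, rng_seed = 5)
  cr <- crossval_shape_regression(ds, "A1", "V-Fix", "AV-A", shape = "C",
                                  B = 30)
  expect_length(cr$rasters, 2L)
  expect_equal(dim(cr$rasters[[1]]$predicted$profiles), c(30L, 6L))
  sm <- smooth_raster(cr$rasters[[1]]$predicted, 0.01)
  expect_s3_class(sm, "binned_raster")
})
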