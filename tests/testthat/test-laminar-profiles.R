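# Brute-force oracle: solve the equivolume depth by numeric quadrature of the
# linearly interpolated area profile.
equivolume_oracle <- function(inner, outer, alpha) {
  area <- function(u) inner + (outer - inner) * u
  total <- stats::integrate(area, 0, 1)$value
  stats::uniroot(function(r) stats::integrate(area, 0, r)$value / total - alpha,
                 c(0, 1), tol = 1e-12)$root
}

test_that("equivolume depths match the quadrature oracle and limit cases", {
  expect_equal(equivolume_depth_fractions(1, 1), ((1:6) - 0.5) / 6)
  expect_equal(equivolume_depth_fractions(2, 2, n = 1), 0.5)
  withr::with_seed(1, {
    for (i in 1:25) {
      inner <- runif(1, 0.2, 3); outer <- runif(1, 0.2, 3)
      f <- equivolume_depth_fractions(inner, outer)
      oracle <- vapply(((1:6) - 0.5) / 6, equivolume_oracle,
                       inner = inner, outer = outer, numeric(1))
      expect_equal(f, oracle, tolerance = 1e-8)
      expect_true(all(diff(f) > 0) && all(f > 0 & f < 1))
    }
  })
  expect_error(equivolume_depth_fractions(-1, 1), "positive")
})

test_that("equivolume fractions converge monotonically to equidistant with area contrast", {
  eq <- ((1:6) - 0.5) / 6
  dev <- vapply(c(2, 1.5, 1.1, 1.01), function(outer) {
    max(abs(equivolume_depth_fractions(1, outer) - eq))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 2e-3)
})

test_that("trilinear sampling is exact on linear fields and matches the corner oracle", {
  # oracle: explicit weighted sum over the 8 surrounding corners
  corner_oracle <- function(vol, p) {
    i0 <- pmin(floor(p), dim(vol) - 1); f <- p - i0
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      s <- s + prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f)) *
        vol[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    s
  }
  zfield <- array(rep(1:6, each = 16), c(4, 4, 6))
  depths <- equivolume_depth_fractions(1, 1)
  prof <- sample_along_normal(zfield, c(2, 2, 1), c(0, 0, 1), depths,
                              thickness = 4)
  expect_equal(prof, 1 + depths * 4, tolerance = 1e-12)
  const <- array(7, c(4, 4, 4))
  expect_equal(sample_along_normal(const, c(2, 2, 1.5), c(0, 0.3, 1), depths),
               rep(7, 6))
  withr::with_seed(2, {
    vol <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
    for (i in 1:20) {
      p <- runif(3, 1, 5)
      expect_equal(laminar:::trilinear_interp(vol, matrix(p, 1)),
                   corner_oracle(vol, p), tolerance = 1e-12)
    }
  })
  # points outside the grid flag as missing
  expect_true(is.na(sample_along_normal(const, c(2, 2, 3.5), c(0, 0, 1),
                                        depths, thickness = 4)[6]))
})

test_that("ROI profiles are vertex medians, robust to skew, 72 per subject", {
  ds <- noiseless_dataset()
  prof <- roi_depth_profile(ds, "A1")
  expect_equal(dim(prof), c(6L, 72L))
  skewed <- manual_dataset(3, function(v, d, lab) c(1, 1, 100)[v])
  expect_equal(unique(as.vector(roi_depth_profile(skewed, "A1"))), 1)
  constant <- manual_dataset(5, function(v, d, lab) 4.2)
  expect_equal(unique(as.vector(roi_depth_profile(constant, "A1"))), 4.2)
  expect_error(roi_depth_profile(ds, "nope"), "empty")
})

test_that("block-wise contrasts implement the printed formulas", {
  ds <- manual_dataset(4, function(v, d, lab) {
    switch(lab$condition, V_AttA = 2, V_AttV = 4, 0)
  })
  prof <- roi_depth_profile(ds, "A1")
  vfix <- compute_contrast(prof, ds$labels, "V-Fix")
  expect_equal(unique(as.vector(vfix$values)), 3)   # (2 + 4) / 2
  expect_equal(ncol(vfix$values), 12L)              # 3 blocks x 4 runs
  # all conditions equal: every difference contrast vanishes
  flat <- manual_dataset(4, function(v, d, lab) 1.5)
  pf <- roi_depth_profile(flat, "A1")
  for (nm in c("AV-A", "AV-V", "AttA-AttV", "AttV-AttA")) {
    expect_equal(unique(as.vector(compute_contrast(pf, flat$labels, nm)$values)),
                 0)
  }
  # attentional contrast divides by 3
  att <- manual_dataset(2, function(v, d, lab) {
    if (lab$attention == "AttA") 3 else 0
  })
  pa <- roi_depth_profile(att, "A1")
  expect_equal(unique(as.vector(compute_contrast(pa, att$labels,
                                                 "AttA-AttV")$values)), 3)
  # missing condition is named in the error
  bad <- ds$labels[ds$labels$condition != "AV_AttA", ]
  expect_error(compute_contrast(prof[, seq_len(nrow(bad))], bad, "AV-A"),
               "AV_AttA")
})

test_that("the laminar shape GLM equals the closed-form orthogonal fit", {
  expect_equal(fit_laminar_glm(rep(3, 6)), list(C = 3, L = 0))
  expect_equal(fit_laminar_glm(0:5), list(C = 2.5, L = 1))
  x <- (1:6) - 3.5
  withr::with_seed(4, {
    for (i in 1:50) {
      y <- rnorm(6)
      f <- fit_laminar_glm(y)
      expect_equal(f$C, mean(y), tolerance = 1e-12)
      expect_equal(f$L, sum(x * y) / sum(x^2), tolerance = 1e-12)
      # affine equivariance: fit(a y + b) = (a C + b, a L)
      a <- runif(1, -2, 2); b <- runif(1, -2, 2)
      g <- fit_laminar_glm(a * y + b)
      expect_equal(g$C, a * f$C + b, tolerance = 1e-10)
      expect_equal(g$L, a * f$L, tolerance = 1e-10)
      # orthogonality: adding a centred-linear component leaves C untouched
      h <- fit_laminar_glm(y + 0.7 * x)
      expect_equal(h$C, f$C, tolerance = 1e-12)
      expect_equal(h$L, f$L + 0.7, tolerance = 1e-12)
    }
  })
  # matrix (mass-univariate) path agrees with the vector path
  withr::with_seed(5, m <- matrix(rnorm(60), 10, 6))
  fm <- fit_laminar_glm(m)
  expect_equal(fm$C[3], fit_laminar_glm(m[3, ])$C)
  expect_equal(fm$L[7], fit_laminar_glm(m[7, ])$L)
  expect_error(fit_laminar_glm(c(1, 2, NA, 4, 5, 6)), "finite")
})
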