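## Smooth a matrix with a separable Gaussian kernel (replicate padding).
## sigma in grid units; sigma <= 0 returns the input unchanged.
smooth_field_2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m1 <- apply(mat, 2, pad_conv)
  t(apply(t(m1), 2, pad_conv))
}

## Seeded smooth Gaussian random field on an nx x ny grid, standardized to
## unit marginal variance (smoothing shrinks the variance; rescale by the
## empirical sd so amplitudes stay comparable across correlation lengths).
gaussian_random_field <- function(nx, ny, corr_length) {
  f <- smooth_field_2d(matrix(stats::rnorm(nx * ny), nx, ny), corr_length)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Generate a synthetic multi-ROI cortical patch
#'
#' Stands in for reconstructed cortical surfaces: each region of interest
#' (bilateral A1, planum temporale, V1, V2/3 by default) is a flat 2D vertex
#' grid carrying a smooth curvature field, inner (white-matter) and outer
#' (pial) cross-sectional area proxies derived from curvature, and — for the
#' visual ROIs — a centre-to-periphery eccentricity coordinate.  All
#' downstream statistics operate on per-vertex scalars, so no mesh topology
#' is represented beyond grid adjacency.
#'
#' @param roi_sizes named list/vector of vertex counts per ROI (each >= 1).
#' @param corr_length curvature correlation length in grid units; 0 gives a
#'   spatially white curvature field.
#' @param curvature_area_gain how strongly curvature modulates the
#'   inner/outer area proxies (kept < 1 so areas stay positive).
#' @param rng_seed integer seed; identical seeds give identical patches.
#' @return an object of class `cortical_patch`: per-ROI list with `coords`
#'   (n x 2), `curvature`, `inner_area`, `outer_area`, and `eccentricity`
#'   for visual ROIs.
#' @export
make_cortical_patch <- function(roi_sizes = list(A1 = 400, PT = 300,
                                                 V1 = 400, V23 = 300),
                                corr_length = 2, curvature_area_gain = 0.5,
                                rng_seed = 1L) {
  roi_sizes <- as.list(roi_sizes)
  if (length(roi_sizes) == 0 || any(unlist(roi_sizes) < 1)) {
    stop("every ROI must have at least one vertex", call. = FALSE)
  }
  if (corr_length < 0) stop("corr_length must be >= 0", call. = FALSE)
  if (abs(curvature_area_gain) >= 1) {
    stop("curvature_area_gain must lie in (-1, 1)", call. = FALSE)
  }
  rois <- with_rng_seed(rng_seed, {
    lapply(seq_along(roi_sizes), function(i) {
      n <- roi_sizes[[i]]
      nx <- max(1L, floor(sqrt(n)))
      ny <- ceiling(n / nx)
      grid <- expand.grid(x = seq_len(nx), y = seq_len(ny))[seq_len(n), ]
      curv_field <- gaussian_random_field(nx, ny, corr_length)
      curv <- curv_field[cbind(grid$x, grid$y)]
      ## curvature-coupled area proxies: gyral crowns (curv > 0) have larger
      ## outer than inner area, sulcal fundi the reverse
      mod <- curvature_area_gain * tanh(curv)
      roi <- list(coords = as.matrix(grid), curvature = curv,
                  inner_area = 1 - mod, outer_area = 1 + mod,
                  nx = nx, ny = ny)
      if (grepl("^V", names(roi_sizes)[i])) {
        cx <- (1 + nx) / 2
        cy <- (1 + ny) / 2
        ecc <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
        roi$eccentricity <- ecc / max(ecc, 1)
      }
      roi
    })
  })
  names(rois) <- names(roi_sizes)
  structure(list(rois = rois, corr_length = corr_length,
                 rng_seed = rng_seed),
            class = "cortical_patch")
}

#' @export
print.cortical_patch <- function(x, ...) {
  sizes <- vapply(x$rois, function(r) length(r$curvature), integer(1))
  cat("<cortical_patch>",
      paste(sprintf("%s:%d", names(sizes), sizes), collapse = " "), "\n")
  invisible(x)
}
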