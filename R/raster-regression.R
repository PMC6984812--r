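#' Per-vertex laminar contrast profiles for an ROI
#'
#' Applies a block-wise contrast at every vertex and depth and averages the
#' block-by-run estimates over the requested runs, yielding one 6-depth
#' profile per vertex (the per-vertex analogue of the ROI median path).
#'
#' @param dataset a `vertex_beta_dataset`.
#' @param roi ROI name.
#' @param spec contrast name or [contrast_spec()].
#' @param runs optional run subset (e.g. one scanning day).
#' @return a vertices x 6 matrix of contrast profiles.
#' @export
vertex_contrast_profiles <- function(dataset, roi, spec, runs = NULL) {
  sel_v <- which(dataset$roi == roi)
  if (length(sel_v) == 0) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  out <- matrix(0, length(sel_v), 6)
  for (d in 1:6) {
    vals <- matrix(dataset$betas[sel_v, d, , drop = FALSE],
                   nrow = length(sel_v))
    ctr <- compute_contrast(vals, dataset$labels, spec, runs = runs)
    out[, d] <- rowMeans(ctr$values)
  }
  out
}

#' Sort vertices by a shape value and average them in percentile-like bins
#'
#' Vertices are ranked by the sorting value (ties broken by vertex index, so
#' the order is stable and reproducible) and partitioned into `B` contiguous
#' rank bins of near-equal size; when the vertex count is not divisible by
#' `B` the earlier bins receive the extra vertices.  Per-bin means of the
#' sorting values and of the supplied profiles are returned.
#'
#' @param sort_values per-vertex sorting values (e.g. a shape parameter of
#'   the predicting contrast).
#' @param profiles per-vertex values to average within bins: a vector or a
#'   vertices x k matrix (e.g. 6-depth profiles).
#' @param B number of bins (`B <=` vertex count).
#' @return an object of class `binned_raster`: `B`, `bin_mean_sort`,
#'   `profiles` (B x k bin means), `bin_sizes`, `order`, `bin_of_vertex`.
#' @export
sort_and_bin <- function(sort_values, profiles, B) {
  n <- length(sort_values)
  if (B > n) stop("more bins than vertices", call. = FALSE)
  if (B < 1) stop("need at least one bin", call. = FALSE)
  if (is.null(dim(profiles))) profiles <- matrix(profiles, ncol = 1)
  if (nrow(profiles) != n) stop("profiles must have one row per vertex",
                                call. = FALSE)
  ord <- order(sort_values, seq_len(n))
  sizes <- rep(floor(n / B), B)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin_of_rank <- rep(seq_len(B), times = sizes)
  bin_of_vertex <- integer(n)
  bin_of_vertex[ord] <- bin_of_rank
  bin_mean_sort <- as.numeric(tapply(sort_values[ord], bin_of_rank, mean))
  prof_binned <- apply(profiles[ord, , drop = FALSE], 2,
                       function(col) tapply(col, bin_of_rank, mean))
  prof_binned <- matrix(prof_binned, nrow = B)
  structure(list(B = B, bin_mean_sort = bin_mean_sort,
                 profiles = prof_binned, bin_sizes = sizes, order = ord,
                 bin_of_vertex = bin_of_vertex),
            class = "binned_raster")
}

## slope/intercept of y on x (closed form); a constant x carries no
## predictive variation, so its slope is 0 by convention
ols_line <- function(x, y) {
  sx <- x - mean(x)
  ssx <- sum(sx^2)
  slope <- if (ssx <= 1e-24 * max(1, mean(x^2))) 0 else sum(sx * y) / ssx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Cross-validated regression of one contrast's laminar shape on another's
#'
#' For each of the two scanning days: the per-vertex shape parameter of the
#' sorting (predicting) contrast is computed from that day's data and the
#' same shape parameter of the predicted contrast from the other day;
#' vertices are sorted and binned by the sorting values; and the predicted
#' bin shape is regressed on the sorting bin shape (slope + intercept).  The
#' leave-one-day-out split removes the selection bias that sorting and
#' evaluating on the same noisy data would induce.  Fold slopes are averaged
#' per subject.
#'
#' @param dataset a `vertex_beta_dataset` with runs on 2 days.
#' @param roi ROI name.
#' @param sorting_spec,predicted_spec contrast names or [contrast_spec()]s.
#' @param shape which shape parameter (`"C"` or `"L"`) to relate.
#' @param B number of bins (default: all vertices, i.e. no binning).
#' @param day_split set `FALSE` to disable the leave-one-day-out split
#'   (anti-pattern, exposed for demonstrating the selection bias).
#' @param compute_rasters also assemble the binned 6-depth display rasters
#'   (disable when only slopes are needed).
#' @return an object of class `shape_regression`: `slope` (fold-averaged),
#'   `per_fold` tibble, `rasters` (per fold: `binned_raster`s of the
#'   sorting and predicted profiles, when computed), `shape`, `B`.
#' @export
crossval_shape_regression <- function(dataset, roi, sorting_spec,
                                      predicted_spec, shape = c("C", "L"),
                                      B = NULL, day_split = TRUE,
                                      compute_rasters = TRUE) {
  shape <- match.arg(shape)
  lab <- dataset$labels
  days <- sort(unique(lab$day))
  if (day_split && length(days) != 2) {
    stop("leave-one-day-out needs exactly 2 days", call. = FALSE)
  }
  n_v <- sum(dataset$roi == roi)
  if (is.null(B)) B <- n_v
  shape_col <- function(spec, runs) {
    prof <- vertex_contrast_profiles(dataset, roi, spec, runs = runs)
    fit_laminar_glm(prof)[[shape]]
  }
  prof6 <- function(spec, runs) {
    vertex_contrast_profiles(dataset, roi, spec, runs = runs)
  }
  folds <- if (day_split) {
    list(list(sort_runs = lab$run[lab$day == days[1]],
              pred_runs = lab$run[lab$day == days[2]]),
         list(sort_runs = lab$run[lab$day == days[2]],
              pred_runs = lab$run[lab$day == days[1]]))
  } else {
    list(list(sort_runs = NULL, pred_runs = NULL))
  }
  per_fold <- list(); rasters <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    s_val <- shape_col(sorting_spec, unique(f$sort_runs))
    p_val <- shape_col(predicted_spec, unique(f$pred_runs))
    bins_p <- sort_and_bin(s_val, p_val, B)
    line <- ols_line(bins_p$bin_mean_sort, bins_p$profiles[, 1])
    per_fold[[fi]] <- tibble::tibble(fold = fi, slope = line$slope,
                                     intercept = line$intercept)
    if (compute_rasters) {
      rasters[[fi]] <- list(
        sorting = sort_and_bin(s_val, prof6(sorting_spec,
                                            unique(f$sort_runs)), B),
        predicted = sort_and_bin(s_val, prof6(predicted_spec,
                                              unique(f$pred_runs)), B))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(slope = mean(per_fold$slope), per_fold = per_fold,
                 rasters = rasters, shape = shape, B = B, roi = roi,
                 subject = dataset$subject),
            class = "shape_regression")
}

#' Group inference on cross-validated raster regression slopes
#'
#' Runs [crossval_shape_regression()] per subject and enters the
#' fold-averaged slopes into a one-sample t-test.  The bin count defaults to
#' the smallest ROI vertex count across subjects.
#'
#' @param datasets list of `vertex_beta_dataset`.
#' @param roi ROI name.
#' @param sorting_spec,predicted_spec contrast names or [contrast_spec()]s.
#' @param shape `"C"` or `"L"`.
#' @param B bin count; `NULL` uses the minimum ROI vertex count.
#' @param day_split see [crossval_shape_regression()].
#' @return a list: `slopes` (per subject), `t`, `df`, `p` (two-sided), `B`.
#' @export
group_raster_slopes <- function(datasets, roi, sorting_spec, predicted_spec,
                                shape = c("C", "L"), B = NULL,
                                day_split = TRUE) {
  shape <- match.arg(shape)
  if (is.null(B)) {
    B <- min(vapply(datasets, function(d) sum(d$roi == roi), integer(1)))
  }
  slopes <- vapply(datasets, function(d) {
    crossval_shape_regression(d, roi, sorting_spec, predicted_spec,
                              shape = shape, B = B, day_split = day_split,
                              compute_rasters = FALSE)$slope
  }, numeric(1))
  tt <- one_sample_t(slopes, "two.sided")
  list(slopes = slopes, t = tt$stat, df = tt$df, p = tt$p, B = B,
       shape = shape, roi = roi)
}

#' Display smoothing of a binned raster along the bin axis
#'
#' Gaussian smoothing of the binned profiles along the vertical (bin) axis
#' with FWHM equal to `fwhm_fraction` of the bin count (1% by default); the
#' kernel is truncated at four standard deviations and renormalized at the
#' edges, so constants are preserved.  Display-only: never feeds statistics.
#'
#' @param raster a [sort_and_bin()] result, or a plain bins x k matrix.
#' @param fwhm_fraction FWHM as a fraction of the number of bins (>= 0).
#' @return the raster with smoothed `profiles` (same class as the input).
#' @export
smooth_raster <- function(raster, fwhm_fraction = 0.01) {
  if (fwhm_fraction < 0) stop("fwhm_fraction must be >= 0", call. = FALSE)
  m <- if (inherits(raster, "binned_raster")) raster$profiles else
    as.matrix(raster)
  B <- nrow(m)
  if (B < 2) stop("need at least 2 bins", call. = FALSE)
  sigma <- fwhm_fraction * B / (2 * sqrt(2 * log(2)))
  if (sigma > 0) {
    r <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    sm <- apply(m, 2, function(col) {
      vapply(seq_len(B), function(i) {
        idx <- max(1, i - r):min(B, i + r)
        kk <- k[idx - i + r + 1]
        sum(kk * col[idx]) / sum(kk)
      }, numeric(1))
    })
    m <- matrix(sm, nrow = B)
  }
  if (inherits(raster, "binned_raster")) {
    raster$profiles <- m
    raster
  } else {
    m
  }
}
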