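#' Equivolume depth fractions for one vertex
#'
#' Places `n` intracortical depths so that each carries the centre of an
#' equal fraction of local cortical volume: depth k sits at the relative
#' depth rho (0 = white-matter boundary, 1 = pial boundary) at which the
#' volume between the white-matter surface and rho equals `(k - 0.5) / n` of
#' the total, with the cross-sectional area interpolating linearly between
#' the inner and outer areas.  The closed form is
#' `rho = (sqrt((1 - a) Ai^2 + a Ao^2) - Ai) / (Ao - Ai)`, reducing to the
#' equidistant grid when the areas are equal (flat cortex).
#'
#' @param inner_area local cross-sectional area at the white-matter surface.
#' @param outer_area local cross-sectional area at the pial surface.
#' @param n number of depths.
#' @param thickness local cortical thickness; fractions are relative depth
#'   and do not depend on it (accepted for interface symmetry).
#' @return strictly increasing depth fractions in (0, 1), deepest first.
#' @export
equivolume_depth_fractions <- function(inner_area, outer_area, n = 6L,
                                       thickness = 1) {
  stopifnot_positive(inner_area = inner_area, outer_area = outer_area,
                     n = n, thickness = thickness)
  a <- (seq_len(n) - 0.5) / n
  if (abs(outer_area - inner_area) < 1e-12 * (outer_area + inner_area)) {
    return(a)
  }
  (sqrt((1 - a) * inner_area^2 + a * outer_area^2) - inner_area) /
    (outer_area - inner_area)
}

#' Trilinear sampling of a 3D volume along a surface normal
#'
#' Samples the volume at `origin + depth_k * thickness * normal` for each
#' depth fraction, by trilinear interpolation over the 8 surrounding grid
#' points (the volume is defined on the integer grid `1..dim`).  Sample
#' points outside the grid yield `NA` so the vertex can be excluded
#' downstream.
#'
#' @param vol 3D numeric array.
#' @param origin length-3 position of the vertex on the white-matter surface,
#'   in voxel coordinates.
#' @param normal length-3 outward normal direction (normalized internally).
#' @param depths depth fractions (e.g. from [equivolume_depth_fractions()]).
#' @param thickness cortical thickness along the normal, in voxel units.
#' @return numeric vector of sampled values, one per depth (`NA` where the
#'   sample point leaves the grid).
#' @export
sample_along_normal <- function(vol, origin, normal, depths, thickness = 1) {
  stopifnot(length(dim(vol)) == 3L, length(origin) == 3L,
            length(normal) == 3L)
  nrm <- normal / sqrt(sum(normal^2))
  pts <- t(vapply(depths, function(d) origin + d * thickness * nrm,
                  numeric(3)))
  trilinear_interp(vol, pts)
}

## Trilinear interpolation of points (rows of pts) in a 3D array on the
## integer grid; points outside [1, dim] give NA.
trilinear_interp <- function(vol, pts) {
  dims <- dim(vol)
  apply(pts, 1, function(p) {
    if (any(p < 1) || any(p > dims)) return(NA_real_)
    i0 <- pmin(floor(p), dims - 1)
    f <- p - i0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      val <- val + w * vol[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    val
  })
}

#' ROI laminar profiles of every beta image
#'
#' Summarizes, per cortical depth, the parameter estimates across all
#' vertices of a (bilateral) ROI by their median — the median rather than
#' the mean because the vertex distribution is skewed, particularly
#' superficially.
#'
#' @param dataset a `vertex_beta_dataset`.
#' @param roi ROI name (must be non-empty in the dataset).
#' @param beta optional beta index; if given, a single 6-value profile.
#' @return a 6 x n_beta matrix of median profiles (or a length-6 vector if
#'   `beta` is given); depth index 1 is the deepest.
#' @export
roi_depth_profile <- function(dataset, roi, beta = NULL) {
  stopifnot(inherits(dataset, "vertex_beta_dataset"))
  sel <- which(dataset$roi == roi)
  if (length(sel) == 0) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  sub <- dataset$betas[sel, , , drop = FALSE]
  keep <- apply(is.finite(sub), 1, all)
  sub <- sub[keep, , , drop = FALSE]
  if (dim(sub)[1] == 0) stop("no vertices with complete depth data",
                             call. = FALSE)
  prof <- apply(sub, c(2, 3), stats::median)
  if (!is.null(beta)) prof[, beta] else prof
}

#' Contrast weights for the six block-wise contrasts of interest
#'
#' Signed weights over the six condition labels for: the unisensory
#' responses versus fixation averaged over attention (`V-Fix`, `A-Fix`, each
#' /2), the crossmodal modulation averaged over attention (`AV-A`, `AV-V`,
#' each /2), and the attentional modulation averaged over the three stimulus
#' types (`AttA-AttV`, `AttV-AttA`, each /3).
#'
#' @param name contrast name.
#' @return an object of class `contrast_spec`: named weight vector plus the
#'   name.
#' @export
contrast_spec <- function(name = c("V-Fix", "A-Fix", "AV-A", "AV-V",
                                   "AttA-AttV", "AttV-AttA")) {
  name <- match.arg(name)
  w <- stats::setNames(numeric(6), CONDITIONS)
  switch(name,
    "V-Fix" = {w[c("V_AttA", "V_AttV")] <- 1 / 2},
    "A-Fix" = {w[c("A_AttA", "A_AttV")] <- 1 / 2},
    "AV-A" = {w[c("AV_AttA", "AV_AttV")] <- 1 / 2
              w[c("A_AttA", "A_AttV")] <- -1 / 2},
    "AV-V" = {w[c("AV_AttA", "AV_AttV")] <- 1 / 2
              w[c("V_AttA", "V_AttV")] <- -1 / 2},
    "AttA-AttV" = {w[c("A_AttA", "V_AttA", "AV_AttA")] <- 1 / 3
                   w[c("A_AttV", "V_AttV", "AV_AttV")] <- -1 / 3},
    "AttV-AttA" = {w[c("A_AttV", "V_AttV", "AV_AttV")] <- 1 / 3
                   w[c("A_AttA", "V_AttA", "AV_AttA")] <- -1 / 3})
  structure(list(name = name, weights = w), class = "contrast_spec")
}

#' Apply a block-wise contrast to labelled beta values
#'
#' Combines the six conditions with the contrast weights within each (block
#' repetition i, run j) cell, yielding 12 block-wise contrast estimates for
#' the default design.  Works identically on ROI median profiles (rows =
#' depths) and on per-vertex values (rows = vertices).
#'
#' @param values numeric matrix with one column per beta image (or a vector
#'   treated as a single row).
#' @param labels the dataset's [beta_labels()] table (must match columns).
#' @param spec a [contrast_spec()] (or a name passed to it).
#' @param runs optional subset of runs to use.
#' @return a list: `values` (rows of the input x blocks-by-run cells) and
#'   `cells` (tibble of block, run, day per column).
#' @export
compute_contrast <- function(values, labels, spec, runs = NULL) {
  if (is.character(spec)) spec <- contrast_spec(spec)
  stopifnot(inherits(spec, "contrast_spec"))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != nrow(labels)) {
    stop("values must have one column per beta image", call. = FALSE)
  }
  if (is.null(runs)) runs <- sort(unique(labels$run))
  active <- names(spec$weights)[spec$weights != 0]
  cells <- unique(labels[labels$run %in% runs, c("block", "run", "day")])
  cells <- cells[order(cells$run, cells$block), ]
  out <- matrix(0, nrow(values), nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    for (cond in active) {
      idx <- which(labels$condition == cond & labels$block == cells$block[ci] &
                     labels$run == cells$run[ci])
      if (length(idx) != 1L) {
        stop(sprintf("missing condition '%s' for block %d run %d", cond,
                     cells$block[ci], cells$run[ci]), call. = FALSE)
      }
      out[, ci] <- out[, ci] + spec$weights[cond] * values[, idx]
    }
  }
  list(values = out, cells = cells, name = spec$name)
}

#' Laminar shape GLM: constant plus linear fit of a 6-depth profile
#'
#' Regresses the profile on a constant and a mean-centred linear depth term
#' (x = -2.5 ... 2.5, one unit per depth step).  Because the regressors are
#' exactly orthogonal, the constant C equals the profile mean and the linear
#' slope L is `sum(x * y) / sum(x^2)`; positive L means an increase toward
#' the cortical surface.  No higher-order (e.g. quadratic) term is modelled.
#'
#' @param profile length-6 numeric vector, or a matrix with 6 columns (one
#'   profile per row; the mass-univariate path).
#' @return for a vector, a list `(C, L)`; for a matrix, a tibble with
#'   columns `C` and `L`.
#' @export
fit_laminar_glm <- function(profile) {
  x <- depth_regressor(6L)
  sxx <- sum(x^2)
  if (is.null(dim(profile))) {
    if (length(profile) != 6L || any(!is.finite(profile))) {
      stop("profile must be 6 finite values", call. = FALSE)
    }
    return(list(C = mean(profile), L = sum(x * profile) / sxx))
  }
  m <- as.matrix(profile)
  if (ncol(m) != 6L) stop("profile matrix must have 6 columns", call. = FALSE)
  if (any(!is.finite(m))) stop("profiles must be finite", call. = FALSE)
  tibble::tibble(C = rowMeans(m), L = as.numeric(m %*% x) / sxx)
}

#' Block-wise laminar contrast profiles and shape parameters for one ROI
#'
#' Convenience wrapper chaining [roi_depth_profile()], [compute_contrast()]
#' and [fit_laminar_glm()]: the 12 block-wise 6-depth contrast profiles of an
#' ROI and their (C, L) shape parameters.
#'
#' @param dataset a `vertex_beta_dataset`.
#' @param roi ROI name.
#' @param spec contrast name or [contrast_spec()].
#' @param runs optional run subset.
#' @return a list: `profiles` (6 x cells), `cells`, `shapes` (tibble with
#'   block, run, day, C, L), `subject`.
#' @export
roi_contrast_shapes <- function(dataset, roi, spec, runs = NULL) {
  prof <- roi_depth_profile(dataset, roi)   # 6 x n_beta, rows = depths
  ctr <- compute_contrast(prof, dataset$labels, spec, runs = runs)
  shapes <- fit_laminar_glm(t(ctr$values))
  list(profiles = ctr$values, cells = ctr$cells,
       shapes = tibble::as_tibble(cbind(ctr$cells, shapes)),
       subject = dataset$subject)
}
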