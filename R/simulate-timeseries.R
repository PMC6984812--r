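#' Simulate voxel time series for one run of the block design
#'
#' Series = design prediction + low-frequency drift + AR(1) noise, at the
#' acquisition geometry of the experiment (TR 3 s, 302 volumes per run for
#' the default design).  The design prediction uses the same design-matrix
#' builder as the first-level fit, so noiseless simulations are recovered
#' exactly.
#'
#' @param design a [build_run_design()] object.
#' @param true_betas numeric vector (one voxel) or matrix (task columns x
#'   voxels) of true block-regressor amplitudes, in design-matrix column
#'   order (see `task_cols` of [build_design_matrix()]).
#' @param run run number to simulate.
#' @param drift_amplitude amplitude of a slow cosine drift added to every
#'   voxel (0 disables).
#' @param ar1_rho AR(1) autocorrelation of the noise, in (-1, 1).
#' @param noise_sd marginal standard deviation of the AR(1) noise (0
#'   disables).
#' @param TR repetition time, seconds.
#' @param rng_seed integer seed.
#' @param dm optional precomputed [build_design_matrix()] for this run.
#' @return a list: `series` (n_vols x voxels matrix), `dm` (the design
#'   matrix used), `true_betas`.
#' @export
simulate_voxel_timeseries <- function(design, true_betas, run = 1L,
                                      drift_amplitude = 0, ar1_rho = 0.3,
                                      noise_sd = 1, TR = 3, rng_seed = 1L,
                                      dm = NULL) {
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(dm)) dm <- build_design_matrix(design, run = run, TR = TR)
  B <- as.matrix(true_betas)
  if (nrow(B) != length(dm$task_cols)) {
    stop("true_betas must have one row per block regressor", call. = FALSE)
  }
  n <- dm$n_vols
  signal <- dm$X[, dm$task_cols, drop = FALSE] %*% B
  t_s <- (seq_len(n) - 1) * TR
  drift <- drift_amplitude * cos(2 * pi * t_s / (n * TR))
  noise <- with_rng_seed(rng_seed, {
    if (noise_sd == 0) {
      matrix(0, n, ncol(B))
    } else {
      innov_sd <- noise_sd * sqrt(1 - ar1_rho^2)
      apply(matrix(stats::rnorm(n * ncol(B), sd = innov_sd), n, ncol(B)), 2,
            function(e) as.numeric(stats::filter(e, ar1_rho,
                                                 method = "recursive")))
    }
  })
  list(series = signal + drift + noise, dm = dm, true_betas = B)
}
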