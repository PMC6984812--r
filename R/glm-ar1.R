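#' Fit a first-level GLM by AR(1) generalized least squares
#'
#' Two-pass estimator: ordinary least squares residuals give a pooled
#' (median-across-voxels) lag-1 autocorrelation estimate; both sides of the
#' model are then prewhitened with the corresponding AR(1) filter and the
#' whitened system is solved by OLS.  With a single voxel the pooled estimate
#' is that voxel's own lag-1 autocorrelation.
#'
#' @param series numeric vector (one voxel) or time-by-voxel matrix.
#' @param X a [build_design_matrix()] object or a plain numeric matrix.
#' @param drop_degenerate drop all-zero event columns before fitting.
#' @return an object of class `glm_ar1`: `beta` (coefficient-by-voxel
#'   matrix), `rho` (pooled AR(1) coefficient), `sigma2` (residual variance
#'   per voxel, whitened scale), `labels`.
#' @export
fit_glm_ar1 <- function(series, X, drop_degenerate = TRUE) {
  if (inherits(X, "design_matrix")) {
    labels <- X$labels
    Xm <- X$X
    if (drop_degenerate && length(X$degenerate) > 0) {
      drop <- c(X$degenerate, paste0(X$degenerate, "_deriv"))
      keep <- !labels %in% drop
      Xm <- Xm[, keep, drop = FALSE]
      labels <- labels[keep]
    }
  } else {
    Xm <- as.matrix(X)
    labels <- colnames(Xm)
    if (is.null(labels)) labels <- sprintf("x%d", seq_len(ncol(Xm)))
  }
  Y <- as.matrix(series)
  if (nrow(Y) != nrow(Xm)) stop("series and design matrix row mismatch",
                                call. = FALSE)
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    bad <- labels[-seq_len(qrX$rank)]
    stop(sprintf("design matrix rank deficient; collinear columns near: %s",
                 paste(utils::head(labels[qrX$pivot[-seq_len(qrX$rank)]], 5),
                       collapse = ", ")), call. = FALSE)
  }
  res <- Y - Xm %*% qr.coef(qrX, Y)
  rho_v <- vapply(seq_len(ncol(res)), function(j) {
    r <- res[, j]
    denom <- sum(r^2)
    ## residuals at numerical zero (noiseless data): no autocorrelation
    if (denom <= 1e-12 * max(1, sum(Y[, j]^2))) 0 else
      sum(r[-1] * r[-length(r)]) / denom
  }, numeric(1))
  rho <- stats::median(rho_v)
  rho <- max(min(rho, 0.999), -0.999)
  W <- function(M) {
    Mw <- M - rho * rbind(0, M[-nrow(M), , drop = FALSE])
    Mw[1, ] <- sqrt(1 - rho^2) * M[1, ]
    Mw
  }
  Xw <- W(Xm); Yw <- W(Y)
  qrW <- qr(Xw)
  beta <- qr.coef(qrW, Yw)
  resw <- Yw - Xw %*% beta
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- colSums(resw^2) / df
  rownames(beta) <- labels
  structure(list(beta = beta, rho = rho, sigma2 = sigma2, labels = labels),
            class = "glm_ar1")
}

#' Retain the activation-block HRF betas of a fitted run
#'
#' Applies the retention rule that only the parameter estimates of the HRF
#' regressors of the stimulation blocks feed the laminar analyses (18 per
#' run, 72 per subject over 4 runs); derivative, target, extra-response,
#' nuisance and drift betas are discarded.
#'
#' @param fit a [fit_glm_ar1()] object.
#' @return matrix of block HRF betas (blocks x voxels) with condition labels
#'   in the row names.
#' @export
activation_block_betas <- function(fit) {
  sel <- grepl("^block_", fit$labels) & !grepl("_deriv$", fit$labels)
  t(t(fit$beta[sel, , drop = FALSE]))
}
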