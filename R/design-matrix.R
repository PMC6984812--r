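#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking at 6 s minus a scaled
#' gamma undershoot peaking around 16 s, normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds).
#' @param dispersion,u_dispersion gamma rate dispersions.
#' @param ratio undershoot ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          dispersion = 1, u_dispersion = 1, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay / dispersion, rate = 1 / dispersion) -
    ratio * stats::dgamma(t, shape = undershoot_delay / u_dispersion,
                          rate = 1 / u_dispersion)
  h[t < 0] <- 0
  h / max(h)
}

#' Discrete cosine drift basis
#'
#' DCT-II regressors with periods at or above the cut-off, excluding the
#' constant: the order is `K = floor(2 * T / cutoff_s)` for a run of total
#' duration `T = n_vols * TR` (a 906 s run at the default 128 s cut-off gives
#' 14 columns).
#'
#' @param n_vols number of volumes.
#' @param TR repetition time, seconds.
#' @param cutoff_s high-pass cut-off period, seconds.
#' @return an `n_vols` x K matrix (K may be 0).
#' @export
dct_drift_basis <- function(n_vols, TR, cutoff_s = 128) {
  stopifnot_positive(n_vols = n_vols, TR = TR, cutoff_s = cutoff_s)
  K <- floor(2 * n_vols * TR / cutoff_s)
  n <- seq_len(n_vols) - 1
  B <- vapply(seq_len(K),
              function(k) sqrt(2 / n_vols) * cos(pi * k * (2 * n + 1) / (2 * n_vols)),
              numeric(n_vols))
  matrix(B, nrow = n_vols)
}

## Convolve onset/duration events with the HRF (and its temporal derivative)
## at microtime resolution dt, then sample at the TR grid.
convolve_events <- function(onsets, durations, n_vols, TR, dt = 0.1,
                            hrf_span = 32) {
  n_fine <- ceiling(n_vols * TR / dt)
  stick <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- max(a, ceiling((onsets[i] + durations[i]) / dt))
    a <- max(1, min(a, n_fine)); b <- min(b, n_fine)
    stick[a:b] <- stick[a:b] + 1
  }
  tg <- seq(0, hrf_span, by = dt)
  h <- canonical_hrf(tg) * dt
  dh <- c(diff(canonical_hrf(tg)), 0)   # derivative (per dt step), same grid
  conv_full <- function(k) {
    z <- stats::convolve(stick, rev(k), type = "open")[seq_len(n_fine)]
    z[floor((seq_len(n_vols) - 1) * TR / dt) + 1]
  }
  cbind(hrf = conv_full(h), deriv = conv_full(dh))
}

#' Build the mixed block-event first-level design matrix for one run
#'
#' Columns, in order: one HRF-convolved regressor per stimulation block (18
#' for the default design), their temporal derivatives, 4 target-event
#' regressors (target modality x attended modality) with derivatives, one
#' extra-response event regressor with derivative, optional nuisance columns,
#' the DCT drift basis (periods >= `drift_cutoff_s`), and a constant.
#'
#' @param design a [build_run_design()] object.
#' @param schedule optional [schedule_targets()] tibble (targets omitted if
#'   `NULL`).
#' @param extra_presses optional numeric vector of extra-response times (s).
#' @param run run number to model.
#' @param TR repetition time, seconds.
#' @param n_vols number of volumes; default covers the run timeline plus
#'   `scan_pad_s` of trailing acquisition (302 for the default design).
#' @param scan_pad_s trailing scanner time beyond the nominal timeline.
#' @param drift_cutoff_s drift high-pass cut-off, seconds.
#' @param nuisance optional numeric matrix of opaque nuisance columns (e.g.
#'   motion parameters).
#' @return an object of class `design_matrix`: `X` (matrix), `labels`
#'   (column labels), `task_cols` (indices of the block HRF columns),
#'   `degenerate` (labels of all-zero event columns), `TR`, `n_vols`.
#' @export
build_design_matrix <- function(design, schedule = NULL, extra_presses = NULL,
                                run = 1L, TR = 3, n_vols = NULL,
                                scan_pad_s = 4, drift_cutoff_s = 128,
                                nuisance = NULL) {
  stopifnot(inherits(design, "run_design"))
  if (is.null(n_vols)) {
    n_vols <- ceiling((design$run_duration_s + scan_pad_s) / TR)
  }
  scan_end <- n_vols * TR
  b <- design$blocks[design$blocks$run == run, ]
  if (nrow(b) == 0) stop("run not present in design", call. = FALSE)
  if (any(b$onset >= scan_end)) {
    warning("events beyond scan end truncated")
    b <- b[b$onset < scan_end, ]
  }
  b <- b[order(b$onset), ]
  rep_idx <- stats::ave(seq_len(nrow(b)),
                        factor(b$condition, levels = CONDITIONS),
                        FUN = seq_along)
  cols <- list(); labs <- character(0); degenerate <- character(0)
  for (i in seq_len(nrow(b))) {
    cv <- convolve_events(b$onset[i], b$duration[i], n_vols, TR)
    cols[[length(cols) + 1L]] <- cv
    labs <- c(labs, sprintf("block_%s_%d", b$condition[i], rep_idx[i]))
  }
  hrf_block <- do.call(cbind, lapply(cols, function(m) m[, 1]))
  der_block <- do.call(cbind, lapply(cols, function(m) m[, 2]))
  ev_cols <- NULL; ev_labs <- character(0)
  if (!is.null(schedule)) {
    s <- schedule[schedule$run == run, ]
    for (tm in c("A", "V")) for (att in c("AttA", "AttV")) {
      lab <- sprintf("target%s_%s", tm, att)
      sel <- s$modality == tm & condition_attention(s$condition) == att
      if (any(sel)) {
        cv <- convolve_events(s$onset[sel], rep(0, sum(sel)), n_vols, TR)
      } else {
        cv <- matrix(0, n_vols, 2)
        degenerate <- c(degenerate, lab)
      }
      ev_cols <- cbind(ev_cols, cv)
      ev_labs <- c(ev_labs, lab, paste0(lab, "_deriv"))
    }
  }
  if (!is.null(extra_presses) && length(extra_presses) > 0) {
    cv <- convolve_events(extra_presses, rep(0, length(extra_presses)),
                          n_vols, TR)
  } else {
    cv <- matrix(0, n_vols, 2)
    degenerate <- c(degenerate, "extra_response")
  }
  ev_cols <- cbind(ev_cols, cv)
  ev_labs <- c(ev_labs, "extra_response", "extra_response_deriv")
  drift <- dct_drift_basis(n_vols, TR, drift_cutoff_s)
  drift_labs <- if (ncol(drift) > 0) sprintf("drift_%02d", seq_len(ncol(drift))) else character(0)
  nuis_labs <- character(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    nuis_labs <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
  }
  X <- cbind(hrf_block, der_block, ev_cols, nuisance, drift, 1)
  labels <- c(labs, paste0(labs, "_deriv"), ev_labs, nuis_labs, drift_labs,
              "constant")
  colnames(X) <- labels
  keep <- labels[!labels %in% c(degenerate, paste0(degenerate, "_deriv"))]
  qr_rank <- qr(X[, keep])$rank
  if (qr_rank < length(keep)) {
    warning("design matrix is rank deficient beyond degenerate event columns")
  }
  structure(list(X = X, labels = labels, task_cols = seq_along(labs),
                 degenerate = degenerate, TR = TR, n_vols = n_vols),
            class = "design_matrix")
}

#' Write a design matrix as TSV with a JSON label sidecar
#'
#' @param dm a [build_design_matrix()] object.
#' @param path TSV output path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  utils::write.table(dm$X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(labels = dm$labels, TR = dm$TR,
                            n_vols = dm$n_vols,
                            degenerate = dm$degenerate),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
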