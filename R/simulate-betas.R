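#' Construct the 72-beta label table of the default design
#'
#' @param design a [build_run_design()] object.
#' @return a tibble with one row per activation-block beta (beta index,
#'   condition, modality, attention, block repetition within run, run, day).
#' @export
beta_labels <- function(design) {
  b <- design$blocks
  b <- b[order(b$run, b$onset), ]
  rep_idx <- stats::ave(seq_len(nrow(b)),
                        interaction(b$run, b$condition, drop = TRUE),
                        FUN = seq_along)
  lab <- tibble::tibble(condition = b$condition,
                        modality = condition_modality(b$condition),
                        attention = condition_attention(b$condition),
                        block = as.integer(rep_idx), run = b$run, day = b$day)
  lab <- lab[order(lab$condition, lab$run, lab$block), ]
  lab$beta <- seq_len(nrow(lab))
  lab[, c("beta", "condition", "modality", "attention", "block", "run", "day")]
}

#' Simulate vertex-by-depth-by-block parameter-estimate datasets
#'
#' Generates, for each subject, the array of per-block GLM parameter
#' estimates (vertex x 6 depths x betas) that the real pipeline would obtain
#' by sampling first-level beta maps along the cortical depth grid.  The
#' generative model per vertex v, depth d and condition:
#'
#' * stimulus-driven response: `g(d) * act(v) * (1 + gamma * w(d))` when the
#'   ROI's preferred modality is present (the attention factor applies only
#'   when the preferred modality is attended) — the superficial-bias gain
#'   `g(d)` and the multiplicative, pattern-preserving attentional gain;
#' * crossmodal deactivation: for the non-preferred unisensory condition the
#'   planted laminar shape `C*(v) + L*(v) * x(d)` is added (in the units the
#'   laminar shape GLM measures, so zero-noise recovery is exact);
#' * crossmodal modulation: audiovisual blocks additionally receive the
#'   patchy sign-varying field `M_C(v) + M_L(v) * x(d)`, whose vertex-wise
#'   correlation with the deactivation field equals `rho_deact_mod` in
#'   expectation;
#' * independent Gaussian block-level noise, plus Gaussian subject random
#'   effects on the planted deactivation shape.
#'
#' @param patch a [make_cortical_patch()] object.
#' @param truth a [ground_truth()] object.
#' @param design a [build_run_design()] object (6 conditions).
#' @param n_subjects number of subjects to simulate.
#' @param rng_seed integer seed.
#' @return a list of `vertex_beta_dataset` objects, one per subject: `betas`
#'   (vertex x 6 x n_beta array), `labels` (see [beta_labels()]), `roi`
#'   (per-vertex ROI name), `subject`, and `truth_fields` (the planted
#'   per-vertex effect fields, for recovery checks).
#' @export
simulate_vertex_betas <- function(patch, truth, design, n_subjects = 11,
                                  rng_seed = 1L) {
  stopifnot(inherits(patch, "cortical_patch"), inherits(truth, "ground_truth"),
            inherits(design, "run_design"))
  labels <- beta_labels(design)
  if (!setequal(unique(labels$condition), CONDITIONS)) {
    stop("design must contain all six conditions", call. = FALSE)
  }
  x <- depth_regressor(6L)
  g <- truth$depth_gain
  w <- truth$attention_depth_weight
  with_rng_seed(rng_seed, {
    lapply(seq_len(n_subjects), function(s) {
      roi_names <- names(patch$rois)
      per_roi <- lapply(roi_names, function(rn) {
        roi <- patch$rois[[rn]]
        n <- length(roi$curvature)
        fam <- roi_family(rn)
        nx <- roi$nx; ny <- roi$ny
        grf <- function() {
          f <- gaussian_random_field(nx, ny, truth$field_corr_length)
          f[roi$coords][seq_len(n)]
        }
        ## subject random effects on the planted deactivation shape
        dC0 <- if (fam == "auditory") truth$deact_C else truth$deact_C_visual
        dL0 <- if (fam == "auditory") truth$deact_L else truth$deact_L_visual
        dC_s <- dC0 + stats::rnorm(1, sd = truth$subject_sd_C)
        dL_s <- dL0 + stats::rnorm(1, sd = truth$subject_sd_L)
        act <- truth$activation_mean + truth$activation_patch_sd * grf()
        zd <- grf()
        zi <- grf()
        rho <- truth$rho_deact_mod
        zm <- rho * zd + sqrt(1 - rho^2) * zi
        dC <- dC_s + truth$deact_patch_sd * zd
        mC <- truth$mod_C + truth$mod_patch_sd * zm
        dL <- rep(dL_s, n)
        mL <- rep(truth$mod_L, n)
        pref <- if (fam == "auditory") "A" else "V"
        att_pref <- if (fam == "auditory") "AttA" else "AttV"
        ## signal: n x 6 x n_beta
        sig <- array(0, dim = c(n, 6L, nrow(labels)))
        for (bi in seq_len(nrow(labels))) {
          mod_lab <- labels$modality[bi]
          att <- labels$attention[bi]
          driven <- mod_lab %in% c(pref, "AV")
          for (d in 1:6) {
            v <- numeric(n)
            if (driven) {
              gain <- g[d] * (1 + if (att == att_pref) {
                truth$attention_gain * w[d]
              } else 0)
              v <- gain * act
            }
            if (mod_lab == setdiff(c("A", "V"), pref)) {
              v <- v + dC + dL * x[d]
            }
            if (mod_lab == "AV") v <- v + mC + mL * x[d]
            sig[, d, bi] <- v
          }
        }
        noise <- array(stats::rnorm(length(sig), sd = truth$noise_sd),
                       dim = dim(sig))
        list(sig = sig + noise, roi = rep(rn, n),
             fields = list(act = act, deact_C = dC, deact_L = dL,
                           mod_C = mC, mod_L = mL,
                           subject_deact_C = dC_s, subject_deact_L = dL_s))
      })
      betas <- do.call(abind3, lapply(per_roi, `[[`, "sig"))
      ds <- structure(list(betas = betas,
                           labels = labels,
                           roi = unlist(lapply(per_roi, `[[`, "roi")),
                           subject = s,
                           truth_fields = stats::setNames(
                             lapply(per_roi, `[[`, "fields"), roi_names)),
                      class = "vertex_beta_dataset")
      validate_vertex_beta_dataset(ds)
      ds
    })
  })
}

## bind arrays along dim 1
abind3 <- function(...) {
  arrs <- list(...)
  d23 <- dim(arrs[[1]])[2:3]
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 1L)), d23))
  at <- 1L
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Validate the structural invariants of a vertex-beta dataset
#'
#' Checks the (vertex x 6 x beta) shape, the labelling of betas as
#' 6 conditions x blocks x runs, the run-to-day mapping, and finiteness.
#'
#' @param ds a `vertex_beta_dataset`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_vertex_beta_dataset <- function(ds) {
  stopifnot(inherits(ds, "vertex_beta_dataset"))
  d <- dim(ds$betas)
  if (length(d) != 3L || d[2] != 6L) {
    stop("betas must be a vertex x 6 x beta array", call. = FALSE)
  }
  lab <- ds$labels
  if (nrow(lab) != d[3]) stop("label table does not match beta count",
                              call. = FALSE)
  counts <- table(lab$condition)
  if (length(unique(counts)) != 1L) {
    stop("conditions must contribute equal numbers of betas", call. = FALSE)
  }
  if (!all(lab$day == ceiling(lab$run / 2))) {
    stop("runs must map to days in consecutive pairs", call. = FALSE)
  }
  if (length(ds$roi) != d[1]) stop("roi vector must match vertex count",
                                   call. = FALSE)
  if (!all(is.finite(ds$betas))) stop("betas must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Write a vertex-beta dataset as plain-text tables
#'
#' Labels and ROI membership as TSV plus one vertex-by-beta TSV matrix per
#' depth, alongside a JSON sidecar with shape metadata.
#'
#' @param ds a `vertex_beta_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_vertex_betas <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ds$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(vertex = seq_along(ds$roi), roi = ds$roi),
                     file.path(dir, "roi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (d in 1:6) {
    utils::write.table(ds$betas[, d, ], file.path(dir, sprintf("betas_depth%d.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  jsonlite::write_json(list(subject = ds$subject, n_vertex = dim(ds$betas)[1],
                            n_depth = 6L, n_beta = dim(ds$betas)[3]),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}
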