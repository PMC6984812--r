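# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

default_design <- function() memo("design", function() build_run_design())

small_patch <- function() {
  memo("patch", function() {
    make_cortical_patch(list(A1 = 80, PT = 64, V1 = 80, V23 = 64),
                        rng_seed = 11)
  })
}

## zero-noise, vertex-constant effects: exact-recovery configuration
noiseless_truth <- function() {
  ground_truth(noise_sd = 0, activation_patch_sd = 0, deact_patch_sd = 0,
               mod_patch_sd = 0, subject_sd_C = 0, subject_sd_L = 0)
}

noiseless_dataset <- function() {
  memo("noiseless_ds", function() {
    simulate_vertex_betas(small_patch(), noiseless_truth(), default_design(),
                          n_subjects = 1, rng_seed = 5)[[1]]
  })
}

noisy_datasets <- function() {
  memo("noisy_ds", function() {
    simulate_vertex_betas(small_patch(), ground_truth(), default_design(),
                          n_subjects = 4, rng_seed = 7)
  })
}

## Hand-built dataset: betas array filled by `fill(vertex, depth, beta_row)`
## over the default 72-beta label table.
manual_dataset <- function(n_vertex, fill, roi = "A1", subject = 1L) {
  labels <- beta_labels(default_design())
  betas <- array(0, dim = c(n_vertex, 6, nrow(labels)))
  for (b in seq_len(nrow(labels))) {
    for (d in 1:6) betas[, d, b] <- fill(seq_len(n_vertex), d, labels[b, ])
  }
  ds <- structure(list(betas = betas, labels = labels,
                       roi = rep(roi, n_vertex), subject = subject,
                       truth_fields = list()),
                  class = "vertex_beta_dataset")
  validate_vertex_beta_dataset(ds)
  ds
}

## Dataset with a planted cross-contrast relation for raster regression:
## per-vertex [V-Fix] constant = s(v); [AV-A] constant = slope * s(v) + e(v);
## independent block-level measurement noise.
planted_raster_dataset <- function(n_vertex, slope, noise_sd = 0.5,
                                   field_sd = 1, resid_sd = 0.3,
                                   rng_seed = 1L, subject = 1L) {
  labels <- beta_labels(default_design())
  withr::with_seed(rng_seed, {
    s <- rnorm(n_vertex, sd = field_sd)
    e <- rnorm(n_vertex, sd = resid_sd)
    betas <- array(rnorm(n_vertex * 6 * nrow(labels), sd = noise_sd),
                   dim = c(n_vertex, 6, nrow(labels)))
  })
  for (b in which(labels$modality == "V")) betas[, , b] <- betas[, , b] + s
  for (b in which(labels$modality == "AV")) {
    betas[, , b] <- betas[, , b] + slope * s + e
  }
  ds <- structure(list(betas = betas, labels = labels,
                       roi = rep("A1", n_vertex), subject = subject,
                       truth_fields = list()),
                  class = "vertex_beta_dataset")
  validate_vertex_beta_dataset(ds)
  ds
}

## Balanced 2 (shape) x 2 (ROI) null group table
null_group_table <- function(n_subjects = 11, sd = 1) {
  tibble::tibble(
    subject = rep(seq_len(n_subjects), each = 4),
    roi = rep(c("primary", "primary", "nonprimary", "nonprimary"),
              n_subjects),
    shape = rep(c("C", "L"), 2 * n_subjects),
    value = rnorm(4 * n_subjects, sd = sd))
}
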