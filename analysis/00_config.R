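# Shared configuration for the analysis scripts.  Every script re-derives
# its inputs deterministically from these seeds, so each stage can be run
# in isolation and in order.

library(laminar)

MASTER_SEED <- 20260926L
N_SUBJECTS <- 11
ROI_SIZES <- list(A1 = 300, PT = 240, V1 = 300, V23 = 240)
RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

make_inputs <- function() {
  design <- build_run_design(rng_seed = stage_seed(MASTER_SEED, 1))
  schedule <- schedule_targets(design, rng_seed = stage_seed(MASTER_SEED, 2))
  patch <- make_cortical_patch(ROI_SIZES, rng_seed = stage_seed(MASTER_SEED, 4))
  datasets <- simulate_vertex_betas(patch, ground_truth(), design,
                                    n_subjects = N_SUBJECTS,
                                    rng_seed = stage_seed(MASTER_SEED, 5))
  list(design = design, schedule = schedule, patch = patch,
       datasets = datasets)
}

save_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
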