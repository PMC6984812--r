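#!/usr/bin/env Rscript
# Stage 2 — first-level GLM demonstration: simulate voxel time series at the
# acquisition geometry (TR 3 s, 302 volumes) with planted block amplitudes,
# AR(1) noise and cosine drift, fit the AR(1)-GLS model, and verify that the
# activation-block betas are recovered.

source(file.path("analysis", "00_config.R"))

inp <- make_inputs()
dm <- build_design_matrix(inp$design, inp$schedule, run = 1)
message(sprintf("design matrix: %d volumes x %d columns (%d block HRF, %d drift)",
                nrow(dm$X), ncol(dm$X), length(dm$task_cols),
                sum(grepl("^drift_", dm$labels))))

set.seed(stage_seed(MASTER_SEED, 6))
n_vox <- 20
true_b <- matrix(rnorm(length(dm$task_cols) * n_vox, sd = 1), ncol = n_vox)
sim <- simulate_voxel_timeseries(inp$design, true_b, run = 1,
                                 drift_amplitude = 2, ar1_rho = 0.3,
                                 noise_sd = 1,
                                 rng_seed = stage_seed(MASTER_SEED, 7),
                                 dm = dm)
fit <- fit_glm_ar1(sim$series, dm)
kept <- activation_block_betas(fit)

recovery <- data.frame(
  voxel = rep(seq_len(n_vox), each = length(dm$task_cols)),
  regressor = rep(rownames(kept), n_vox),
  true = as.vector(true_b), estimated = as.vector(kept))
save_tsv(recovery, "first_level_recovery.tsv")
message(sprintf("pooled AR(1) rho-hat = %.3f; beta RMSE = %.3f over %d voxels",
                fit$rho, sqrt(mean((kept - true_b)^2)), n_vox))
message(sprintf("retained %d block betas per run (72 per subject over 4 runs)",
                nrow(kept)))
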