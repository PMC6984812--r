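#!/usr/bin/env Rscript
# Stage 1 — build the experimental design, schedule the targets, score a
# simulated observer, and generate the synthetic vertex-by-depth datasets.

source(file.path("analysis", "00_config.R"))

inp <- make_inputs()

message(sprintf("design: %d runs x %d blocks, %d stimuli/block",
                inp$design$params$n_runs, sum(inp$design$blocks$run == 1),
                inp$design$stimuli_per_block))
message(sprintf("targets per condition x modality: %d",
                table(inp$schedule$condition, inp$schedule$modality)[1, 1]))

write_events_tsv(inp$design, inp$schedule, run = 1,
                 path = file.path(RESULTS_DIR, "run1_events.tsv"))

## simulated observer: responds to ~95% of attended-modality targets with a
## 0.2-1.2 s latency; unattended targets are ignored
set.seed(stage_seed(MASTER_SEED, 3))
sch <- inp$schedule
hit <- sch$modality == substr(sub("^.*_Att", "Att", sch$condition), 4, 4)
sel <- which(hit & runif(nrow(sch)) < 0.95)
presses <- data.frame(run = sch$run[sel],
                      time = sch$onset[sel] + runif(length(sel), 0.2, 1.2))
score <- score_responses(inp$schedule, presses)
save_tsv(score, "behavior_scores.tsv")
message(sprintf("extra-responses: %d of %d presses",
                attr(score, "extra_responses"), attr(score, "n_presses")))

save_tsv(inp$datasets[[1]]$labels, "beta_labels.tsv")
message(sprintf("simulated %d subjects, %d betas each, ROIs: %s",
                length(inp$datasets), dim(inp$datasets[[1]]$betas)[3],
                paste(names(ROI_SIZES), unlist(ROI_SIZES), sep = ":",
                      collapse = " ")))
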