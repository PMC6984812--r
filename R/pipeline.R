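#' Default configuration of an end-to-end synthetic experiment
#'
#' Bundles every knob of the pipeline: master seed, design parameters
#' (reproducing the experiment's constants), ROI sizes, ground-truth
#' parameters, number of subjects, and analysis toggles.  The master seed is
#' expanded into per-stage sub-seeds with [stage_seed()], so stages can be
#' re-run in isolation.
#'
#' @param seed master integer seed.
#' @param n_subjects number of simulated subjects.
#' @param roi_sizes named vertex counts for A1, PT, V1, V23.
#' @param design a [design_params()] list.
#' @param truth a [ground_truth()] object.
#' @param blockwise_group enter block-wise shape values into the group model
#'   instead of subject-level means.
#' @param similarity_depth `"pooled"` or a depth index for the pattern-
#'   similarity analysis.
#' @param output_dir directory for stage outputs (`NULL` keeps everything in
#'   memory).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 11,
                            roi_sizes = list(A1 = 300, PT = 240,
                                             V1 = 300, V23 = 240),
                            design = design_params(),
                            truth = ground_truth(),
                            blockwise_group = FALSE,
                            similarity_depth = "pooled",
                            output_dir = NULL) {
  structure(list(seed = seed, n_subjects = n_subjects, roi_sizes = roi_sizes,
                 design = design, truth = truth,
                 blockwise_group = blockwise_group,
                 similarity_depth = similarity_depth,
                 output_dir = output_dir),
            class = "pipeline_config")
}

write_stage_tsv <- function(df, dir, name) {
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}

#' Run the full synthetic laminar analysis pipeline
#'
#' simulate -> first-level demonstration -> laminar profiles -> group
#' step-down inference -> per-depth decoding and pattern similarity ->
#' raster regression, deterministically from the configured seed.  Stage
#' outputs are written as TSV/JSON under `output_dir` when configured and
#' collected in the returned report.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `design`, `schedule`, `behavior`,
#'   `first_level`, `shape_tables`, `stepdown`, `decoding`, `similarity`,
#'   `raster`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  seed <- config$seed

  ## --- design and behaviour ------------------------------------------------
  design <- build_run_design(config$design, rng_seed = stage_seed(seed, 1))
  schedule <- schedule_targets(design, rng_seed = stage_seed(seed, 2))
  ## simulated observer: responds to most attended-modality targets
  presses <- with_rng_seed(stage_seed(seed, 3), {
    hit <- schedule$modality == substr(condition_attention(schedule$condition),
                                       4, 4)
    sel <- which(hit & stats::runif(nrow(schedule)) < 0.95)
    data.frame(run = schedule$run[sel],
               time = schedule$onset[sel] + stats::runif(length(sel), 0.2, 1.2))
  })
  behavior <- score_responses(schedule, presses)
  write_stage_tsv(behavior, out_dir, "behavior.tsv")

  ## --- synthetic datasets --------------------------------------------------
  patch <- make_cortical_patch(config$roi_sizes,
                               rng_seed = stage_seed(seed, 4))
  datasets <- simulate_vertex_betas(patch, config$truth, design,
                                    n_subjects = config$n_subjects,
                                    rng_seed = stage_seed(seed, 5))

  ## --- first-level demonstration on simulated voxel time series -----------
  dm <- build_design_matrix(design, schedule, run = 1)
  true_b <- matrix(stats::rnorm(length(dm$task_cols) * 3, sd = 1),
                   ncol = 3)
  sim <- simulate_voxel_timeseries(design, true_b, run = 1, ar1_rho = 0.3,
                                   noise_sd = 1,
                                   rng_seed = stage_seed(seed, 6), dm = dm)
  fit <- fit_glm_ar1(sim$series, sim$dm)
  first_level <- list(rho_hat = fit$rho,
                      beta_rmse = sqrt(mean((fit$beta[dm$task_cols, ] -
                                               true_b)^2)),
                      n_block_betas_per_run = length(dm$task_cols),
                      n_retained_betas_per_subject =
                        nrow(datasets[[1]]$labels))

  ## --- laminar profiles and shape tables ----------------------------------
  families <- list(
    auditory = list(rois = c(primary = "A1", nonprimary = "PT"),
                    deact = "V-Fix", mod = "AV-A", att = "AttA-AttV"),
    visual = list(rois = c(primary = "V1", nonprimary = "V23"),
                  deact = "A-Fix", mod = "AV-V", att = "AttV-AttA"))
  shape_tables <- list(); stepdown <- list(); stepdown_rows <- list()
  for (fam in names(families)) {
    fd <- families[[fam]]
    for (kind in c("deact", "mod", "att")) {
      tab <- group_shape_table(datasets, fd$rois, fd[[kind]],
                               blockwise = config$blockwise_group)
      shape_tables[[paste(fam, kind, sep = "_")]] <- tab
      side <- if (kind == "deact") c(C = "less", L = "two.sided") else
        c(C = "two.sided", L = "two.sided")
      res <- stepdown_test(tab, sidedness = side)
      stepdown[[paste(fam, kind, sep = "_")]] <- res
      stepdown_rows[[length(stepdown_rows) + 1L]] <-
        stepdown_table(res, contrast = paste(fam, fd[[kind]]))
    }
  }
  write_stage_tsv(do.call(rbind, stepdown_rows), out_dir, "stepdown.tsv")

  ## --- decoding ------------------------------------------------------------
  decoding <- list()
  dec_plan <- list(A1 = "AV_vs_A", PT = "AV_vs_A",
                   V1 = "AV_vs_V", V23 = "AV_vs_V")
  for (roi in names(dec_plan)) {
    for (cmp in unique(c(dec_plan[[roi]], "AttA_vs_AttV"))) {
      accs <- vapply(datasets,
                     function(d) decode_per_depth(d, roi, cmp)$accuracy,
                     numeric(6))
      decoding[[paste(roi, cmp, sep = "_")]] <-
        list(mean_accuracy = rowMeans(accs), per_subject = accs)
    }
  }

  ## --- pattern similarity in A1 -------------------------------------------
  sim_contrasts <- vapply(datasets, function(d) {
    pattern_similarity(d, "A1", depth = config$similarity_depth)$contrast
  }, numeric(1))
  similarity <- list(contrasts = sim_contrasts,
                     p = exact_sign_permutation(sim_contrasts))

  ## --- raster regression ---------------------------------------------------
  raster <- list(
    PT_C = group_raster_slopes(datasets, "PT", "V-Fix", "AV-A", shape = "C"),
    A1_L = group_raster_slopes(datasets, "A1", "V-Fix", "AV-A", shape = "L"))

  provenance <- list(seed = seed, n_subjects = config$n_subjects,
                     n_betas_per_subject = nrow(datasets[[1]]$labels),
                     roi_sizes = lapply(config$roi_sizes, identity),
                     config_json = jsonlite::toJSON(
                       list(seed = seed, n_subjects = config$n_subjects,
                            roi_sizes = config$roi_sizes,
                            blockwise_group = config$blockwise_group),
                       auto_unbox = TRUE))
  report <- structure(list(design = design, schedule = schedule,
                           behavior = behavior, first_level = first_level,
                           shape_tables = shape_tables, stepdown = stepdown,
                           decoding = decoding, similarity = similarity,
                           raster = raster, datasets = datasets,
                           provenance = provenance),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(first_level = first_level,
                              similarity_p = similarity$p,
                              provenance = provenance[c("seed", "n_subjects",
                                                        "n_betas_per_subject")]),
                         file.path(out_dir, "report.json"), auto_unbox = TRUE)
  }
  report
}
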