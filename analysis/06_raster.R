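#!/usr/bin/env Rscript
# Stage 6 — raster regression: does the laminar shape of the visual-induced
# deactivation [V-Fix] in a vertex predict its crossmodal modulation [AV-A]?
# Leave-one-day-out sorting/binning with group inference on the slopes, and
# a smoothed group raster for display.

source(file.path("analysis", "00_config.R"))

inp <- make_inputs()

for (spec in list(list(roi = "PT", shape = "C"),
                  list(roi = "A1", shape = "L"))) {
  gr <- group_raster_slopes(inp$datasets, spec$roi, "V-Fix", "AV-A",
                            shape = spec$shape)
  message(sprintf("%s [%s]: %d bins, mean slope %.3f, t(%d) = %.2f, p = %.4g",
                  spec$roi, spec$shape, gr$B, mean(gr$slopes), gr$df, gr$t,
                  gr$p))
  save_tsv(data.frame(subject = seq_along(gr$slopes), roi = spec$roi,
                      shape = spec$shape, slope = gr$slopes),
           sprintf("raster_slopes_%s_%s.tsv", spec$roi, spec$shape))
}

## group display raster for PT (constant): average the smoothed per-subject
## binned profiles of the predicted contrast
B <- min(vapply(inp$datasets, function(d) sum(d$roi == "PT"), integer(1)))
rasters <- lapply(inp$datasets, function(ds) {
  cr <- crossval_shape_regression(ds, "PT", "V-Fix", "AV-A", shape = "C",
                                  B = B)
  (smooth_raster(cr$rasters[[1]]$predicted, 0.01)$profiles +
     smooth_raster(cr$rasters[[2]]$predicted, 0.01)$profiles) / 2
})
group_raster <- Reduce(`+`, rasters) / length(rasters)
save_tsv(as.data.frame(group_raster), "raster_PT_predicted_AVA.tsv")
message(sprintf("group raster: %d bins x 6 depths written", B))
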