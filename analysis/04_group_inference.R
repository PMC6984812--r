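#!/usr/bin/env Rscript
# Stage 4 — group inference: 2 (shape) x 2 (ROI) step-down testing of the
# deactivation, crossmodal-modulation and attention contrasts, separately
# for the auditory and visual cortices, with a-priori one-sided tests for
# the deactivation constants.

source(file.path("analysis", "00_config.R"))

inp <- make_inputs()
families <- list(
  auditory = list(rois = c(primary = "A1", nonprimary = "PT"),
                  contrasts = c(deactivation = "V-Fix",
                                modulation = "AV-A",
                                attention = "AttA-AttV")),
  visual = list(rois = c(primary = "V1", nonprimary = "V23"),
                contrasts = c(deactivation = "A-Fix",
                              modulation = "AV-V",
                              attention = "AttV-AttA")))

rows <- list()
for (fam in names(families)) {
  fd <- families[[fam]]
  for (kind in names(fd$contrasts)) {
    tab <- group_shape_table(inp$datasets, fd$rois, fd$contrasts[[kind]])
    side <- if (kind == "deactivation") c(C = "less", L = "two.sided") else
      c(C = "two.sided", L = "two.sided")
    res <- stepdown_test(tab, sidedness = side)
    message(sprintf("%s %s [%s]: stage1 F(%g,%g)=%.2f p=%.4g; stages run: %s",
                    fam, kind, fd$contrasts[[kind]], res$stage1$df1,
                    res$stage1$df2, res$stage1$stat, res$stage1$p,
                    paste(res$gating, collapse = ",")))
    rows[[length(rows) + 1L]] <-
      stepdown_table(res, contrast = paste(fam, fd$contrasts[[kind]]))
  }
}
save_tsv(do.call(rbind, rows), "stepdown_tables.tsv")
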