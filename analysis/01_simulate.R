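#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates 8 NR (no rejection) and 24 CR (chronic rejection) ROIs at desk
# scale (300 x 300 px, 1 um/px) with the default phenotype mixes: NR has
# sparse, spatially isolated immune cells; CR has dense immune aggregates
# with a planted Macrophage-2 / CTL-2 spatial attraction (adjacency 0.8).
# Writes the channel stacks, ground-truth masks, and the true phenotype
# table under results/run/.

library(imcscope)

seed <- 1L
out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- default_panel()
write_panel(panel, file.path(out, "panel.csv"))

cohort <- generate_cohort(8, 24, seed = seed)

ptab <- list()
for (id in names(cohort)) {
  sim <- cohort[[id]]
  write_roi(sim$roi, file.path(out, paste0(id, "_stack.tiff")))
  write_mask(sim$truth$true_mask, file.path(out, paste0(id, "_true_mask.tiff")))
  write_mask(sim$truth$nucleus_mask,
             file.path(out, paste0(id, "_true_nuclei.tiff")))
  ptab[[id]] <- data.frame(
    roi_id = id, cell_id = seq_along(sim$truth$phenotype_of_cell),
    phenotype = sim$truth$phenotype_of_cell, cohort = sim$truth$cohort)
}
ptab <- do.call(rbind, ptab)
data.table::fwrite(ptab, file.path(out, "true_phenotypes.csv"))

cat(sprintf("simulated %d ROIs (%d NR / %d CR), %d cells total\n",
            length(cohort), 8, 24, nrow(ptab)))
imm <- ptab$phenotype != "not immune cell"
cat(sprintf("immune cells: %d (%d in CR, %d in NR)\n", sum(imm),
            sum(imm & ptab$cohort == "CR"), sum(imm & ptab$cohort == "NR")))
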