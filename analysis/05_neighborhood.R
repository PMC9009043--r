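#!/usr/bin/env Rscript
# Stage 5: spatial neighborhood permutation analysis.
#
# Per ROI: neighbor graph at a 4 px (4 um) dilation radius over the
# segmented masks, then the immune-focused pairwise permutation test (5000
# permutations, alpha 0.01, labels permuted over immune cells). Cohort
# aggregation signs interactions (+) and avoidances (-) so they cancel.

library(imcscope)

seed <- 5L
out <- "results/run"
panel <- read_panel(file.path(out, "panel.csv"))
cells <- read_cell_table(file.path(out, "cells.csv"), panel)
asg <- data.table::fread(file.path(out, "cluster_assignment.csv"))
phen <- asg$phenotype
imm_ph <- sort(unique(phen[phen != "not immune cell"]))
ids <- unique(cells$roi_id)

res <- list()
for (id in ids) {
  mask <- read_mask(file.path(out, paste0(id, "_mask.tiff")))
  g <- build_neighbor_graph(mask, 4)
  sel <- cells$roi_id == id
  lab <- phen[sel][match(g$cells, cells$cell_id[sel])]
  res[[id]] <- permutation_test(
    g, lab, phenotypes = imm_ph, n_perm = 5000, alpha = 0.01,
    permutable = lab != "not immune cell",
    seed = derive_seed(seed, match(id, ids)), roi_id = id)
}
res <- do.call(rbind, res)
data.table::fwrite(res, file.path(out, "neighborhood_results.csv"))

for (grp in c("NR", "CR")) {
  part <- res[grepl(paste0("^", grp), res$roi_id), ]
  summ <- summarize_cohort(part, alpha = 0.01)
  data.table::fwrite(summ, file.path(
    out, sprintf("neighborhood_summary_%s.csv", grp)))
  n_sig <- sum(part$verdict != "none", na.rm = TRUE)
  cat(sprintf("%s: %d significant (ROI, pair) results over %d testable; %d pairs with nonzero cohort score\n",
              grp, n_sig, sum(!is.na(part$verdict)),
              sum(summ$score_pct != 0, na.rm = TRUE)))
}
top <- summarize_cohort(res[grepl("^CR", res$roi_id), ], alpha = 0.01)
top <- top[order(-top$score_pct), ]
cat("strongest CR interactions:\n")
print(head(top[, c("pheno_a", "pheno_b", "n_testable", "score_pct")], 5),
      row.names = FALSE)
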