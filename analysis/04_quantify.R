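#!/usr/bin/env Rscript
# Stage 4: per-ROI quantification and NR-vs-CR comparison.
#
# Median marker signal per ROI (over all cells), immune subpopulation
# counts/proportions (non-immune cells excluded from the denominator),
# within-subpopulation z-scores across ROIs, and two-sided Wilcoxon
# rank-sum comparisons with BH q-values alongside the raw p-values.

library(imcscope)

out <- "results/run"
panel <- read_panel(file.path(out, "panel.csv"))
cells <- read_cell_table(file.path(out, "cells.csv"), panel)
asg <- data.table::fread(file.path(out, "cluster_assignment.csv"))
stopifnot(identical(asg$cell_id, cells$cell_id))
cohort_of <- c(NR = "NR", CR = "CR")[sub("-.*", "", unique(cells$roi_id))]
names(cohort_of) <- unique(cells$roi_id)

med <- median_marker_per_roi(cells, panel$marker, cohort_of)
props <- immune_proportions(cells, asg$phenotype, cohort_of = cohort_of)
zc <- standardize_counts(props$counts)

cmp_prop <- compare_cohorts(props$proportions)
data.table::fwrite(med, file.path(out, "roi_median_markers.csv"))
data.table::fwrite(props$counts, file.path(out, "roi_immune_counts.csv"))
data.table::fwrite(props$proportions,
                   file.path(out, "roi_immune_proportions.csv"))
data.table::fwrite(data.frame(roi_id = rownames(zc), zc,
                              check.names = FALSE),
                   file.path(out, "roi_count_zscores.csv"))
data.table::fwrite(cmp_prop, file.path(out, "cohort_proportion_tests.csv"))

sig <- cmp_prop[!is.na(cmp_prop$p) & cmp_prop$p < 0.05, ]
cat("subpopulations with shifted proportions (Wilcoxon p < 0.05):\n")
print(sig[order(sig$p), c("variable", "median_NR", "median_CR", "p", "q")],
      digits = 3, row.names = FALSE)
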