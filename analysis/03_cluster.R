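#!/usr/bin/env Rscript
# Stage 3: Phenograph meta-clustering, annotation, tSNE.
#
# Pools all segmented cells, clusters them on the raw per-cell mean
# intensities of all 10 panel markers (exact kNN, k = 75, Jaccard edge
# weights, seeded Louvain), builds the cluster x marker median profile with
# its column-standardized heatmap z-scores, calls immune clusters, and
# embeds a subsample with tSNE (perplexity 30).

library(imcscope)

seed <- 3L
out <- "results/run"
panel <- read_panel(file.path(out, "panel.csv"))
cells <- read_cell_table(file.path(out, "cells.csv"), panel)

asg <- phenograph_cluster(cells, panel$marker, k = 75, seed = seed)
prof <- profile_clusters(cells, asg, panel$marker)
asg <- annotate_immune(prof, asg, panel)

cat(sprintf("%d meta-clusters, %d immune (%d immune cells of %d)\n",
            length(asg$sizes), sum(asg$immune),
            sum(asg$cell_phenotype != "not immune cell"), nrow(cells)))
print(asg$phenotype)

data.table::fwrite(
  data.frame(roi_id = cells$roi_id, cell_id = cells$cell_id,
             meta_cluster = asg$cluster, phenotype = asg$cell_phenotype),
  file.path(out, "cluster_assignment.csv"))
data.table::fwrite(
  data.frame(cluster = rownames(prof$medians),
             phenotype = unname(asg$phenotype), prof$medians,
             check.names = FALSE),
  file.path(out, "cluster_profile_medians.csv"))
data.table::fwrite(
  data.frame(cluster = rownames(prof$z), prof$z, check.names = FALSE),
  file.path(out, "cluster_profile_z.csv"))

# tSNE on a subsample (the embedding is for visualization only)
set.seed(seed)
sub <- sample(nrow(cells), min(2000L, nrow(cells)))
y <- tsne_embed(cells[sub, ], panel$marker, perplexity = 30, seed = seed)
data.table::fwrite(
  data.frame(roi_id = cells$roi_id[sub], cell_id = cells$cell_id[sub],
             tsne1 = y[, 1], tsne2 = y[, 2],
             phenotype = asg$cell_phenotype[sub]),
  file.path(out, "tsne.csv"))
cat("wrote cluster assignment, profiles and tSNE coordinates\n")
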