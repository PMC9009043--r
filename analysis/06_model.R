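#!/usr/bin/env Rscript
# Stage 6: cohort modeling.
#
# PCA (centered, unit-variance scaled) on the per-ROI features -- median
# marker signal plus immune subpopulation counts, constant columns dropped --
# then a Wilcoxon rank-sum test on PC1 by cohort, a logistic regression of
# chronic rejection on PC1 (ridge fallback under complete separation), and
# the marker correlation network (Spearman, |r| >= 0.8).

library(imcscope)

out <- "results/run"
panel <- read_panel(file.path(out, "panel.csv"))
med <- as.data.frame(data.table::fread(file.path(out, "roi_median_markers.csv")))
cnt <- as.data.frame(data.table::fread(file.path(out, "roi_immune_counts.csv")))

x <- cbind(med[, c("roi_id", immune_markers(panel))],
           cnt[match(med$roi_id, cnt$roi_id),
               !(names(cnt) %in% c("roi_id", "cohort")), drop = FALSE])
flat <- vapply(x, function(v) is.numeric(v) && stats::sd(v) == 0, logical(1))
if (any(flat)) {
  cat("dropping constant features:", paste(names(x)[flat], collapse = ", "),
      "\n")
  x <- x[, !flat, drop = FALSE]
}

pca <- pca_fit(x, scale = TRUE)
cat(sprintf("PC1 explains %.2f%% of the variance (PC2: %.2f%%)\n",
            pca$explained_var_pct[1], pca$explained_var_pct[2]))
test <- pc1_test(pca, med$cohort)
cat(sprintf("PC1 NR-vs-CR Wilcoxon rank-sum p = %.3g\n", test$p))
lr <- logistic_pc1(pca, med$cohort)
cat(sprintf("logistic on PC1%s: %d/%d ROIs at correct-class probability >= 0.75, %d outliers\n",
            if (lr$separation) " (ridge fallback, complete separation)" else "",
            lr$n_correct_ge_075, length(lr$prob), lr$n_outliers))

net <- correlation_network(x, method = "spearman", threshold = 0.8)
cat(sprintf("correlation network: %d edges at |rho| >= 0.8\n", nrow(net)))

data.table::fwrite(data.frame(roi_id = med$roi_id, cohort = med$cohort,
                              pca$scores, check.names = FALSE),
                   file.path(out, "pca_scores.csv"))
data.table::fwrite(data.frame(variable = rownames(pca$contrib_pct),
                              pca$contrib_pct, check.names = FALSE),
                   file.path(out, "pca_contributions.csv"))
data.table::fwrite(net, file.path(out, "network_edges.csv"))
jsonlite::write_json(list(
  explained_var_pct = pca$explained_var_pct,
  pc1_wilcoxon_p = test$p,
  logistic = list(intercept = lr$intercept, slope = lr$slope,
                  ridge = lr$ridge, separation = lr$separation,
                  n_correct_ge_075 = lr$n_correct_ge_075,
                  n_outliers = lr$n_outliers, accuracy = lr$accuracy)),
  file.path(out, "model_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
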