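#!/usr/bin/env Rscript
# Stage 2: single-cell segmentation.
#
# Hot-pixel filtering, 2x upscaling, three-class pixel classification
# (trained once, on sparse labels sampled from the first ROI's ground
# truth -- the scripted stand-in for interactive brush labelling), watershed
# nuclei segmentation, cell expansion, 1x rescaling and per-cell
# measurement. Writes the cell masks and the pooled cell table.

library(imcscope)

seed <- 2L
out <- "results/run"
panel <- read_panel(file.path(out, "panel.csv"))
truth <- data.table::fread(file.path(out, "true_phenotypes.csv"))
ids <- unique(truth$roi_id)
params <- segmentation_params()

# train the pixel classifier on the first ROI
first <- ids[1]
roi1 <- read_roi(file.path(out, paste0(first, "_stack.tiff")), panel,
                 roi_id = first)
tr <- list(true_mask = read_mask(file.path(out, paste0(first, "_true_mask.tiff"))),
           nucleus_mask = read_mask(file.path(out, paste0(first, "_true_nuclei.tiff"))))
labs <- training_labels_from_truth(tr, 2000, seed = seed)
clf <- train_pixel_classifier(
  upscale2x(remove_hot_pixels(roi1, params$hotpixel_factor)$stack),
  labs, seed = seed)

tabs <- list()
for (id in ids) {
  roi <- read_roi(file.path(out, paste0(id, "_stack.tiff")), panel,
                  roi_id = id)
  seg <- segment_roi(roi, clf, params)
  write_mask(seg$mask, file.path(out, paste0(id, "_mask.tiff")))
  tabs[[id]] <- seg$cells
  tm <- read_mask(file.path(out, paste0(id, "_true_mask.tiff")))
  mm <- match_cells(tm, seg$mask, 0.5)
  cat(sprintf("%s: %d cells segmented, recall %.1f%% at IoU >= 0.5\n",
              id, nrow(seg$cells), 100 * nrow(mm) / max(tm)))
}
cells <- do.call(rbind, tabs)
write_cell_table(cells, file.path(out, "cells.csv"), panel)
cat(sprintf("total: %d cells across %d ROIs\n", nrow(cells), length(ids)))
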