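test_that("hot-pixel removal replaces outliers by the local median", {
  const <- matrix(7, 20, 20)
  expect_identical(remove_hot_pixels(const, 5), const)

  field <- matrix(10, 15, 15)
  field[8, 8] <- 1000
  out <- remove_hot_pixels(field, 5)
  expect_identical(out[8, 8], 10)            # hand-computed 3x3 median
  expect_identical(out[1, 1], 10)

  zeros <- matrix(0, 10, 10); zeros[4, 7] <- 50
  out <- remove_hot_pixels(zeros, 5)
  expect_true(all(out == 0))
  # idempotent on isolated outliers
  expect_identical(remove_hot_pixels(out, 5), out)
})

test_that("2x upscaling and mask downscaling honour their contracts", {
  m <- matrix(seq_len(16), 4, 4)
  up <- upscale2x(m)
  expect_identical(dim(up), c(8L, 8L))

  mask <- matrix(0L, 20, 20); mask[6:11, 6:11] <- 3L   # one 6x6 cell at 2x
  down <- downscale_mask(mask)
  expect_identical(sort(unique(as.integer(down))), c(0L, 3L))
  expect_true(sum(down == 3L) %in% 7:9)      # ~9 block samples, edge effects

  m1 <- fix_nr_sim()$truth$true_mask
  expect_identical(downscale_mask(upscale_mask2x(m1)), m1)
})

test_that("pixel classifier training is seeded, accurate, and fail-fast", {
  sim <- fix_nr_sim()
  up <- upscale2x(remove_hot_pixels(sim$roi, 5)$stack)
  labs <- training_labels_from_truth(sim$truth, 800, seed = 2)
  clf <- train_pixel_classifier(up, labs, max_per_class = 800, ntree = 40,
                                seed = 9)
  probs <- predict_probabilities(clf, up)
  sums <- probs$nuclear + probs$cytoplasm_membrane + probs$background
  expect_lt(max(abs(sums - 1)), 1e-6)

  # held-out accuracy vs ground-truth classes on fresh pixels
  truth_cls <- matrix(3L, nrow(up[1, , ]), ncol(up[1, , ]))
  truth_cls[upscale_mask2x(sim$truth$true_mask) > 0L] <- 2L
  truth_cls[upscale_mask2x(sim$truth$nucleus_mask) > 0L] <- 1L
  set.seed(1)
  held <- sample(which(labs == 0L), 4000)
  pred_cls <- max.col(cbind(as.numeric(probs$nuclear[held]),
                            as.numeric(probs$cytoplasm_membrane[held]),
                            as.numeric(probs$background[held])))
  expect_gt(mean(pred_cls == truth_cls[held]), 0.9)

  # determinism: same seed, same predictions
  clf2 <- train_pixel_classifier(up, labs, max_per_class = 800, ntree = 40,
                                 seed = 9)
  probs2 <- predict_probabilities(clf2, up)
  expect_identical(probs$nuclear, probs2$nuclear)

  # a class with no labels is a training error naming the class
  labs_nobg <- labs; labs_nobg[labs_nobg == 3L] <- 0L
  expect_error(train_pixel_classifier(up, labs_nobg), "background",
               class = "imc_training_error")

  # channel mismatch at prediction time
  expect_error(predict_probabilities(clf, up[1:9, , ]),
               class = "imc_format_error")
})

test_that("segmentation separates analytic disks and handles empty input", {
  blank <- structure(list(nuclear = matrix(0, 64, 64),
                          cytoplasm_membrane = matrix(0, 64, 64),
                          background = matrix(1, 64, 64)),
                     class = "pixel_probabilities")
  expect_identical(max(segment_cells(blank)), 0L)

  # two disks 20 px apart -> two cells, no shared pixels
  nuc <- make_disk_mask(rbind(c(20, 20), c(20, 40)), c(4, 4), 64, 64)
  cyto <- make_disk_mask(rbind(c(20, 20), c(20, 40)), c(8, 8), 64, 64)
  probs <- structure(list(nuclear = (nuc > 0) * 1,
                          cytoplasm_membrane = (cyto > 0 & nuc == 0) * 1,
                          background = (cyto == 0) * 1),
                     class = "pixel_probabilities")
  m <- segment_cells(probs)
  expect_identical(length(setdiff(unique(as.integer(m)), 0L)), 2L)
  # each output cell maps to exactly one input disk
  expect_identical(length(unique(m[nuc == 1])), 1L)
  expect_identical(length(unique(m[nuc == 2])), 1L)
})

test_that("oracle probabilities recover the exact planted cell count", {
  sim <- fix_nr_sim()
  probs <- structure(list(
    nuclear = (upscale_mask2x(sim$truth$nucleus_mask) > 0L) * 1,
    cytoplasm_membrane = (upscale_mask2x(sim$truth$true_mask) > 0L &
                            upscale_mask2x(sim$truth$nucleus_mask) == 0L) * 1,
    background = (upscale_mask2x(sim$truth$true_mask) == 0L) * 1),
    class = "pixel_probabilities")
  mask <- compact_labels(downscale_mask(segment_cells(probs)))
  expect_identical(max(mask), length(sim$truth$phenotype_of_cell))
})

test_that("per-cell measurement is exact arithmetic on pixels", {
  mask <- matrix(0L, 5, 5); mask[2, 1:5] <- 1L
  stack <- array(0, c(1, 5, 5)); stack[1, 2, ] <- 1:5
  panel <- marker_panel(c("M"), c("nuclear"))
  tab <- measure_cells(mask, stack, panel)
  expect_identical(tab$area_px, 5L)
  expect_identical(tab$M, 3)
  expect_identical(tab$centroid_row, 1)      # 0-based
  expect_identical(tab$centroid_col, 2)

  empty <- measure_cells(matrix(0L, 5, 5), stack, panel)
  expect_identical(nrow(empty), 0L)
  expect_error(measure_cells(matrix(0L, 4, 4), stack, panel),
               class = "imc_format_error")
})

test_that("measured marker means track the planted expression draws", {
  sim <- fix_cr_sim()
  tab <- measure_cells(sim$truth$true_mask, sim$roi)
  planted <- sim$truth$expression[tab$cell_id, "CD3"]
  keep <- planted > 0
  rho <- cor(tab$CD3[keep], planted[keep], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("the dilation neighbor graph matches brute force", {
  # 3 px gap at radius 4 -> neighbors; 10 px gap -> not
  m <- make_disk_mask(rbind(c(15, 10), c(15, 21)), c(4, 4), 40, 60)
  # boundary gap = 11 - 4 - 4 = 3
  g <- build_neighbor_graph(m, 4)
  expect_identical(nrow(g$edges), 1L)
  m2 <- make_disk_mask(rbind(c(15, 10), c(15, 28)), c(4, 4), 40, 60)
  expect_identical(nrow(build_neighbor_graph(m2, 4)$edges), 0L)
  single <- make_disk_mask(rbind(c(10, 10)), 3, 20, 20)
  expect_identical(nrow(build_neighbor_graph(single, 4)$edges), 0L)

  # randomized instance vs brute-force minimum boundary distance
  sim <- simulate_roi(tissue_sim_config("NR", roi_shape_px = c(120, 120),
                                        n_nonimmune = 30, n_immune = 10,
                                        seed = 21))
  g <- build_neighbor_graph(sim$truth$true_mask, 4)
  bf <- brute_force_neighbors(sim$truth$true_mask, 4)
  expect_identical(unname(g$edges), unname(bf))
})

test_that("learned segmentation recovers planted cells one to one", {
  sim <- fix_cr_sim()
  labs <- training_labels_from_truth(sim$truth, 2000, seed = 4)
  up <- upscale2x(remove_hot_pixels(sim$roi, 5)$stack)
  clf <- train_pixel_classifier(up, labs, seed = 4)
  seg <- segment_roi(sim$roi, clf)
  n_true <- length(sim$truth$phenotype_of_cell)
  mm <- match_cells(sim$truth$true_mask, seg$mask, 0.5)
  expect_gt(nrow(mm) / n_true, 0.95)
  expect_lt(max(mm$centroid_err_px), 2)
  expect_identical(nrow(seg$cells), max(seg$mask))
})
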