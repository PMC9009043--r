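test_that("per-ROI medians follow the stated conventions", {
  cells <- data.frame(roi_id = c(rep("a", 3), rep("b", 4)),
                      cell_id = 1:7,
                      CD8 = c(1, 2, 9, 1, 2, 3, 4))
  med <- median_marker_per_roi(cells, "CD8")
  expect_equal(med$CD8, c(2, 2.5))           # odd n, and mean-of-middle-two
  shuffled <- cells[c(3, 6, 1, 7, 4, 2, 5), ]
  med2 <- median_marker_per_roi(shuffled, "CD8")
  expect_equal(med2$CD8[match(med$roi_id, med2$roi_id)], med$CD8)
})

test_that("immune proportions exclude non-immune cells and handle zeros", {
  cells <- data.frame(roi_id = c(rep("a", 6), rep("b", 2)), cell_id = 1:8)
  ph <- c("CTL-2", "CTL-2", "CTL-2", "Macrophage-2", "not immune cell",
          "not immune cell", "not immune cell", "not immune cell")
  pr <- immune_proportions(cells, ph)
  expect_equal(pr$proportions[1, "CTL-2"], 0.75)
  expect_equal(pr$proportions[1, "Macrophage-2"], 0.25)
  expect_true(all(is.na(pr$proportions[2, c("CTL-2", "Macrophage-2")])))
  # proportions sum to one where defined
  expect_equal(sum(pr$proportions[1, c("CTL-2", "Macrophage-2")]), 1)
  expect_identical(unname(pr$totals), c(4, 0))
})

test_that("count standardization uses population SD over ROIs", {
  counts <- data.frame(roi_id = c("a", "b", "c"), s1 = c(2, 2, 2),
                       s2 = c(0, 10, 5))
  z <- standardize_counts(counts)
  expect_equal(unname(z[, "s1"]), c(0, 0, 0))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  two <- data.frame(roi_id = c("a", "b"), s2 = c(0, 10))
  expect_equal(unname(standardize_counts(two)[, "s2"]), c(-1, 1))
  expect_error(standardize_counts(counts[1, ]), class = "imc_config_error")
})

test_that("Wilcoxon comparisons use the exact small-sample null", {
  f <- data.frame(cohort = rep(c("NR", "CR"), each = 3),
                  v = c(1, 2, 3, 4, 5, 6))
  out <- compare_cohorts(f, "v")
  expect_equal(out$p, 0.1)                   # exact: 2/C(6,3) * 2-sided
  # symmetry under label swap
  f2 <- f; f2$cohort <- rev(f2$cohort)
  expect_equal(compare_cohorts(f2, "v")$p, 0.1)
  # identical groups carry no evidence
  f3 <- data.frame(cohort = rep(c("NR", "CR"), each = 3), v = rep(2, 6))
  expect_equal(compare_cohorts(f3, "v")$p, 1)
  expect_error(compare_cohorts(data.frame(cohort = "NR", v = 1), "v"),
               class = "imc_config_error")
})

test_that("the rank-sum test is calibrated under the null", {
  # both cohorts drawn from the same feature distribution (shift = 1)
  hits <- 0
  for (r in 1:200) {
    f <- simulate_marker_features(8, 24, shift = 1, seed = 5000 + r)
    hits <- hits + (compare_cohorts(f, "CD3")$p < 0.05)
  }
  rate <- hits / 200
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("planted CR enrichment is recovered directionally", {
  # per-ROI immune proportions from ground-truth labels across a small cohort
  small_nr <- tissue_sim_config("NR", roi_shape_px = c(160, 160),
                                n_nonimmune = 70, n_immune = 30)
  small_cr <- tissue_sim_config("CR", roi_shape_px = c(160, 160),
                                n_nonimmune = 55, n_immune = 70,
                                aggregate_sd_px = 18)
  coh <- generate_cohort(6, 6, seed = 31, nr_config = small_nr,
                         cr_config = small_cr)
  cells <- list(); phen <- list()
  for (id in names(coh)) {
    tab <- measure_cells(coh[[id]]$truth$true_mask, coh[[id]]$roi,
                         roi_id = id)
    cells[[id]] <- tab
    phen[[id]] <- coh[[id]]$truth$phenotype_of_cell[tab$cell_id]
  }
  cells <- do.call(rbind, cells)
  cohort_of <- vapply(coh, function(s) s$truth$cohort, character(1))
  pr <- immune_proportions(cells, unlist(phen), cohort_of = cohort_of)
  cmp <- compare_cohorts(pr$proportions, c("Macrophage-2", "CTL-2"))
  # CR-enriched subpopulations: higher CR median and significant rank-sum
  expect_true(all(cmp$median_CR > cmp$median_NR))
  expect_true(all(cmp$p < 0.05))
})

test_that("cohort composition identities are simple arithmetic", {
  cs <- composition_summary(c(NR = 100, CR = 300), c(NR = 10, CR = 90))
  expect_identical(cs$total, 400)
  expect_identical(cs$total_immune, 100)
  expect_equal(unname(cs$share_of_immune_pct["CR"]), 90)
  expect_equal(unname(cs$immune_fraction_of_cohort_pct["NR"]), 10)
  expect_error(composition_summary(c(NR = 5), c(NR = 6)),
               class = "imc_value_error")
})
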