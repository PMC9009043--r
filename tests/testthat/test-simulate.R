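test_that("default profiles encode the expected immunophenotypes", {
  profs <- default_profiles()
  expect_length(profs, 12L)
  expect_identical(sum(vapply(profs, `[[`, logical(1), "immune")), 11L)
  # macrophages never express CD3
  expect_identical(profs[["Macrophage-1"]]$marker_means[["CD3"]], 0)
  expect_identical(profs[["Macrophage-2"]]$marker_means[["CD3"]], 0)
  # every cell type has a nucleus
  for (p in profs) expect_gt(p$marker_means[["Iridium"]], 0)
  # hepatocytes express no immune marker
  hep <- profs[["not immune cell"]]
  expect_false(hep$immune)
  expect_true(all(hep$marker_means[immune_markers(default_panel())] == 0))
  # CTLs are CD45+/CD3+/CD8+
  for (nm in c("CTL-1", "CTL-2"))
    expect_true(all(profs[[nm]]$marker_means[c("CD45", "CD3", "CD8")] > 0))
  expect_error(phenotype_profile("x", TRUE, c(NotAMarker = 1, Iridium = 5)),
               "NotAMarker", class = "imc_config_error")
})

test_that("simulation is deterministic and seeds differentiate", {
  cfg <- tissue_sim_config("CR", seed = 11)
  a <- simulate_roi(cfg); b <- simulate_roi(cfg)
  expect_identical(a$roi$stack, b$roi$stack)
  expect_identical(a$truth$true_mask, b$truth$true_mask)
  c2 <- simulate_roi(tissue_sim_config("CR", seed = 12))
  expect_false(identical(a$truth$true_mask, c2$truth$true_mask))
})

test_that("empty tissue yields pure-noise background and an empty mask", {
  cfg <- tissue_sim_config("NR", n_nonimmune = 0, n_immune = 0,
                           roi_shape_px = c(64, 64), seed = 1)
  sim <- simulate_roi(cfg)
  expect_true(all(sim$truth$true_mask == 0L))
  expect_length(sim$truth$phenotype_of_cell, 0L)
  expect_true(all(sim$roi$stack >= 0))
})

test_that("ground truth is a consistent oracle: labels, phenotypes, gaps", {
  sim <- fix_cr_sim()
  labs <- sort(unique(sim$truth$true_mask[sim$truth$true_mask > 0L]))
  expect_identical(labs, seq_along(sim$truth$phenotype_of_cell))
  # nuclei sit inside their own cell
  nm <- sim$truth$nucleus_mask
  inside <- nm == 0L | nm == sim$truth$true_mask
  expect_true(all(inside))
  # immune mix matches the configured probabilities within binomial error
  cfg <- tissue_sim_config("CR", seed = 11)
  ph <- sim$truth$phenotype_of_cell
  imm <- ph[ph != "not immune cell"]
  for (nm2 in c("CTL-2", "Macrophage-2")) {
    p <- cfg$phenotype_mix[[nm2]]
    se <- sqrt(p * (1 - p) / length(imm))
    expect_lt(abs(mean(imm == nm2) - p), 4 * se + 0.02)
  }
})

test_that("overcrowded configurations fail with a density error", {
  cfg <- tissue_sim_config("NR", n_nonimmune = 5000, n_immune = 0,
                           roi_shape_px = c(80, 80), seed = 1)
  expect_error(simulate_roi(cfg), "density", class = "imc_simulation_error")
})

test_that("config invariants are enforced", {
  bad_mix <- default_mix("NR"); bad_mix[1] <- bad_mix[1] + 0.5
  expect_error(tissue_sim_config("NR", phenotype_mix = bad_mix),
               "sum to 1", class = "imc_config_error")
  expect_error(tissue_sim_config("NR", roi_shape_px = c(32, 300)),
               ">= 64", class = "imc_config_error")
  expect_error(tissue_sim_config(
    "CR", planted_pairs = list(list(a = "CTL-2", b = "CTL-1", prob = 1.4))),
    class = "imc_config_error")
})

test_that("cohort generation derives per-ROI seeds from the master seed", {
  small_nr <- tissue_sim_config("NR", roi_shape_px = c(100, 100),
                                n_nonimmune = 25, n_immune = 8)
  small_cr <- tissue_sim_config("CR", roi_shape_px = c(100, 100),
                                n_nonimmune = 20, n_immune = 20,
                                aggregate_sd_px = 15)
  coh <- generate_cohort(2, 2, seed = 7, nr_config = small_nr,
                         cr_config = small_cr)
  expect_length(coh, 4L)
  expect_identical(names(coh), c("NR-1", "NR-2", "CR-1", "CR-2"))
  expect_identical(vapply(coh, function(s) s$truth$cohort, character(1)),
                   c("NR-1" = "NR", "NR-2" = "NR",
                     "CR-1" = "CR", "CR-2" = "CR"))
  # distinct ROIs differ; identical master seed reproduces
  expect_false(identical(coh[["NR-1"]]$truth$true_mask,
                         coh[["NR-2"]]$truth$true_mask))
  coh2 <- generate_cohort(2, 2, seed = 7, nr_config = small_nr,
                          cr_config = small_cr)
  expect_identical(coh[["CR-2"]]$roi$stack, coh2[["CR-2"]]$roi$stack)
  coh3 <- generate_cohort(2, 2, seed = 8, nr_config = small_nr,
                          cr_config = small_cr)
  expect_false(identical(coh[["NR-1"]]$truth$true_mask,
                         coh3[["NR-1"]]$truth$true_mask))
})

test_that("the planted pair is recovered by the neighborhood oracle", {
  sim <- fix_cr_sim()
  g <- build_neighbor_graph(sim$truth$true_mask, 4)
  res <- permutation_test(
    g, sim$truth$phenotype_of_cell, phenotypes = names(default_mix("CR")),
    n_perm = 2000, alpha = 0.01,
    permutable = sim$truth$phenotype_of_cell != "not immune cell",
    seed = 5)
  hit <- res[res$pheno_a == "Macrophage-2" & res$pheno_b == "CTL-2", ]
  expect_lt(hit$p_high, 0.01)
  expect_identical(hit$verdict, "interaction")
})
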