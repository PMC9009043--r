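test_that("phenograph respects planted blob structure", {
  set.seed(8)
  x <- rbind(matrix(rnorm(200 * 4, 0), 200, 4),
             matrix(rnorm(200 * 4, 10), 200, 4))
  cells <- as.data.frame(x); names(cells) <- paste0("m", 1:4)
  truth <- rep(1:2, each = 200)
  # with k comparable to the blob size, the blobs are recovered exactly
  asg <- phenograph_cluster(cells, names(cells), k = 100, seed = 1)
  expect_identical(length(asg$sizes), 2L)
  expect_equal(rand_index_adj(asg$cluster, truth), 1.0)
  # with small k, modularity sub-splits the sparse kNN graph, but every
  # community stays inside one blob (the partition refines the truth)
  asg15 <- phenograph_cluster(cells, names(cells), k = 15, seed = 1)
  purity <- vapply(split(truth, asg15$cluster),
                   function(v) length(unique(v)), integer(1))
  expect_true(all(purity == 1L))
  # determinism
  asg2 <- phenograph_cluster(cells, names(cells), k = 15, seed = 1)
  expect_identical(asg15$cluster, asg2$cluster)
  # modularity beats the trivial one-cluster partition (Q = 0)
  expect_gt(asg15$modularity, 0)
})

test_that("degenerate clustering inputs are handled", {
  cells <- data.frame(m1 = rep(1, 10), m2 = rep(2, 10))
  expect_warning(asg <- phenograph_cluster(cells, c("m1", "m2"), k = 75,
                                           seed = 1),
                 "lowering k")
  expect_identical(length(asg$sizes), 1L)
  expect_error(phenograph_cluster(cells, c("m1", "m2"), k = 0),
               class = "imc_config_error")
})

test_that("tSNE is deterministic, separates blobs, and guards perplexity", {
  set.seed(2)
  x <- rbind(matrix(rnorm(150 * 3, 0), 150, 3),
             matrix(rnorm(150 * 3, 10), 150, 3))
  cells <- as.data.frame(x); names(cells) <- c("m1", "m2", "m3")
  y <- tsne_embed(cells, names(cells), n_iter = 350, seed = 5)
  expect_identical(y, tsne_embed(cells, names(cells), n_iter = 350, seed = 5))
  grp <- rep(1:2, each = 150)
  cent <- rbind(colMeans(y[grp == 1, ]), colMeans(y[grp == 2, ]))
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- mean(sqrt(c(rowSums(sweep(y[grp == 1, ], 2, cent[1, ])^2),
                        rowSums(sweep(y[grp == 2, ], 2, cent[2, ])^2))))
  expect_gt(between / within, 3)
  expect_warning(tsne_embed(cells[1:50, ], names(cells), n_iter = 20,
                            seed = 1),
                 "perplexity lowered")
  bad <- cells; bad$m1[3] <- NA
  expect_error(tsne_embed(bad, names(cells)), class = "imc_value_error")
})

test_that("cluster profiles use medians and population-SD z-scores", {
  cells <- data.frame(CD3 = c(0, 0, 0, 10, 10, 10), other = 1)
  asg <- structure(list(cluster = rep(1:2, each = 3), sizes = c(3L, 3L)),
                   class = "cluster_assignment")
  prof <- profile_clusters(cells, asg, c("CD3", "other"))
  expect_equal(unname(prof$medians[, "CD3"]), c(0, 10))
  expect_equal(unname(prof$z[, "CD3"]), c(-1, 1))  # population SD 5
  expect_equal(unname(prof$z[, "other"]), c(0, 0)) # zero-SD column

  one <- structure(list(cluster = rep(1L, 6), sizes = 6L),
                   class = "cluster_assignment")
  expect_true(all(profile_clusters(cells, one, c("CD3", "other"))$z == 0))

  # permutation invariance of the medians
  ord <- c(4, 2, 6, 1, 3, 5)
  asg_p <- structure(list(cluster = asg$cluster[ord], sizes = c(3L, 3L)),
                     class = "cluster_assignment")
  expect_equal(profile_clusters(cells[ord, ], asg_p,
                                c("CD3", "other"))$medians, prof$medians)
})

test_that("immune annotation applies the marker-pattern rules", {
  sim_profile <- function(med) {
    structure(list(medians = med, z = zscore_columns(med)),
              class = "cluster_profile")
  }
  mk <- default_panel()$marker
  med <- matrix(0, 6, length(mk), dimnames = list(1:6, mk))
  med[, "Iridium"] <- 25
  med[1, c("CD45", "CD3", "CD8")] <- c(15, 20, 18)   # CTL, larger
  med[2, c("CD45", "CD3", "CD8")] <- c(8, 35, 40)    # CTL, smaller
  med[3:6, "Collagen1"] <- c(4, 2, 3, 1)             # structural: not immune
  asg <- structure(list(cluster = rep(1:6, c(500, 200, 80, 80, 80, 80)),
                        sizes = c(500L, 200L, 80L, 80L, 80L, 80L)),
                   class = "cluster_assignment")
  out <- annotate_immune(sim_profile(med), asg)
  expect_identical(unname(out$phenotype[1:2]), c("CTL-1", "CTL-2"))
  expect_identical(unname(out$immune), c(TRUE, TRUE, rep(FALSE, 4)))
  expect_true(all(out$phenotype[3:6] == "not immune cell"))

  # an all-hepatocyte profile has no immune clusters
  z0 <- matrix(0, 2, length(mk), dimnames = list(1:2, mk))
  z0[, "Iridium"] <- 25
  asg0 <- structure(list(cluster = rep(1:2, c(5, 5)), sizes = c(5L, 5L)),
                    class = "cluster_assignment")
  out0 <- annotate_immune(sim_profile(z0), asg0)
  expect_true(all(!out0$immune))
  expect_true(all(out0$cell_phenotype == "not immune cell"))

  p_noimm <- marker_panel(c("Collagen1", "Iridium"),
                          c("structural", "nuclear"))
  expect_error(annotate_immune(sim_profile(z0), asg0, p_noimm),
               class = "imc_config_error")
})

test_that("clustering plus annotation recovers the planted phenotypes", {
  fx <- fix_balanced_cells()
  panel <- default_panel()
  asg <- phenograph_cluster(fx$cells, panel$marker, k = 75, seed = 7)
  prof <- profile_clusters(fx$cells, asg, panel$marker)
  asg <- annotate_immune(prof, asg, panel)
  # partition agreement with the simulator truth
  expect_gt(rand_index_adj(asg$cell_phenotype, fx$truth), 0.9)
  # all 11 immune phenotype labels present
  expect_setequal(setdiff(unique(asg$phenotype), "not immune cell"),
                  names(default_mix("NR")))
  # macrophage clusters show CD3 below the immune threshold
  mac <- grepl("^Macrophage", asg$phenotype)
  expect_true(all(prof$z[mac, "CD3"] < 1))
  # exhaustive, disjoint partition
  expect_identical(sum(asg$sizes), nrow(fx$cells))
})
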