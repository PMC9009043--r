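test_that("the pair statistic is the mean neighbor count and asymmetric", {
  # star graph: one A cell touching three B cells
  g <- structure(list(edges = cbind(a = c(1L, 1L, 1L), b = 2:4),
                      cells = 1:4), class = "neighbor_graph")
  lab <- c("A", "B", "B", "B")
  expect_equal(pair_statistic(g, lab, "A", "B"), 3)
  expect_equal(pair_statistic(g, lab, "B", "A"), 1)

  # two A cells with 1 and 3 B-neighbors -> mean 2
  g2 <- structure(list(edges = cbind(a = c(1L, 2L, 2L, 2L), b = c(3L, 4L, 5L, 6L)),
                       cells = 1:6), class = "neighbor_graph")
  lab2 <- c("A", "A", "B", "B", "B", "B")
  expect_equal(pair_statistic(g2, lab2, "A", "B"), 2)

  empty <- structure(list(edges = matrix(integer(0), 0, 2), cells = 1:3),
                     class = "neighbor_graph")
  expect_equal(pair_statistic(empty, c("A", "A", "B"), "A", "B"), 0)
  expect_true(is.na(pair_statistic(empty, c("A", "A", "B"), "C", "A")))
})

test_that("single-phenotype ROIs are inert: all p-values are 1", {
  g <- structure(list(edges = cbind(a = 1:3, b = 2:4), cells = 1:4),
                 class = "neighbor_graph")
  res <- permutation_test(g, rep("A", 4), n_perm = 50, seed = 1)
  expect_true(all(res$p_high == 1))
  expect_true(all(res$p_low == 1))
  expect_true(all(res$verdict == "none"))
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  m <- make_disk_mask(rbind(c(8, 8), c(8, 14), c(20, 20), c(20, 26),
                            c(32, 8), c(32, 32), c(8, 32)),
                      rep(2, 7), 40, 40)
  g <- build_neighbor_graph(m, 4)
  lab <- c("A", "B", "A", "B", "B", "A", "B")
  ex <- enumeration_test(g, lab)
  mc <- permutation_test(g, lab, n_perm = 10000, seed = 9)
  cmp <- merge(ex, mc, by = c("pheno_a", "pheno_b"))
  for (side in c("p_high", "p_low")) {
    pe <- cmp[[paste0(side, ".x")]]
    pm <- cmp[[paste0(side, ".y")]]
    se <- sqrt(pe * (1 - pe) / 10000)
    expect_true(all(abs(pm - pe) <= 3 * se + 2 / 10001))
  }
})

test_that("p-values are never zero and the streams are matched and seeded", {
  sim <- fix_cr_sim()
  g <- build_neighbor_graph(sim$truth$true_mask, 4)
  lab <- sim$truth$phenotype_of_cell
  r1 <- permutation_test(g, lab, n_perm = 200, seed = 3)
  r2 <- permutation_test(g, lab, n_perm = 200, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p_high > 0 & r1$p_low > 0))
  expect_true(all(r1$p_high <= 1 & r1$p_low <= 1))
  # at most one verdict per pair at any alpha
  expect_false(any(r1$p_high < 0.05 & r1$p_low < 0.05))
})

test_that("eleven phenotypes give 121 ordered pair hypotheses", {
  ph <- names(default_mix("NR"))
  expect_identical(nrow(enumerate_pairs(ph)), 121L)
  sim <- fix_cr_sim()
  g <- build_neighbor_graph(sim$truth$true_mask, 4)
  res <- permutation_test(g, sim$truth$phenotype_of_cell,
                          phenotypes = ph, n_perm = 20, seed = 1)
  expect_identical(nrow(res), 121L)
})

test_that("cohort aggregation signs and cancels verdicts", {
  mk <- function(roi, ph, pl) data.frame(
    roi_id = roi, pheno_a = "A", pheno_b = "B", n_a = 3L, n_b = 3L,
    observed_stat = 1, p_high = ph, p_low = pl,
    verdict = ifelse(ph < 0.01, "interaction",
                     ifelse(pl < 0.01, "avoidance", "none")))
  res <- rbind(mk("r1", 0.001, 1), mk("r2", 0.001, 1),
               mk("r3", 1, 0.001), mk("r4", 0.5, 0.5))
  s <- summarize_cohort(res, alpha = 0.01)
  expect_equal(s$score_pct, 25)              # (2 - 1) / 4
  s2 <- summarize_cohort(res[1:2, ], alpha = 0.01)
  expect_equal(s2$score_pct, 100)
  s3 <- summarize_cohort(res[2:3, ], alpha = 0.01)
  expect_equal(s3$score_pct, 0)              # one + and one - cancel
  # untestable pair: statistic missing in every ROI
  res$observed_stat <- NA_real_
  expect_true(is.na(summarize_cohort(res, 0.01)$score_pct))
})

test_that("null one-tailed p-values are valid (never anti-conservative)", {
  masks <- lapply(1:3, function(i)
    simulate_roi(tissue_sim_config("CR", seed = 300 + i))$truth$true_mask)
  graphs <- lapply(masks, build_neighbor_graph, radius_px = 4)
  set.seed(77)
  phen <- paste0("P", 1:5)
  rates <- numeric(0)
  for (rep in 1:36) {
    g <- graphs[[(rep - 1) %% 3 + 1]]
    lab <- sample(phen, length(g$cells), replace = TRUE)
    res <- permutation_test(g, lab, phenotypes = phen, n_perm = 999,
                            alpha = 0.05, seed = 4000 + rep)
    ok <- !is.na(res$observed_stat)
    rates <- c(rates, (sum(res$p_high[ok] < 0.05) +
                         sum(res$p_low[ok] < 0.05)) / (2 * sum(ok)))
  }
  rate <- mean(rates)
  se <- stats::sd(rates) / sqrt(length(rates))
  # super-uniform by construction of the +1 estimator: at most alpha,
  # approaching it as the statistic's ties thin out
  expect_lte(rate, 0.05 + 2 * se)
  expect_gt(rate, 0)
})
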