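#' Mean neighbor count for one ordered phenotype pair
#'
#' The observed neighborhood statistic for the ordered pair (a, b): the mean,
#' over cells of phenotype a, of their number of phenotype-b neighbors. A
#' cell is never its own neighbor, but a = b is a valid self-pair (b
#' neighbors of other b cells). Undefined (NA) when no a cell is present.
#'
#' @param graph a `neighbor_graph` from [build_neighbor_graph()].
#' @param labels phenotype labels, parallel to `graph$cells`.
#' @param a,b phenotype names.
#' @return numeric scalar (NA if a is absent).
#' @export
pair_statistic <- function(graph, labels, a, b) {
  stopifnot(length(labels) == length(graph$cells))
  na <- sum(labels == a)
  if (na == 0) return(NA_real_)
  e <- graph$edges
  if (!nrow(e)) return(0)
  ia <- match(e[, 1], graph$cells); ib <- match(e[, 2], graph$cells)
  la <- labels[ia]; lb <- labels[ib]
  (sum(la == a & lb == b) + sum(lb == a & la == b)) / na
}

#' Pairwise neighborhood permutation test for one ROI
#'
#' For every ordered phenotype pair, tests whether cells of phenotype b are
#' found next to cells of phenotype a more (interaction) or less (avoidance)
#' often than under random relabelling. The null is generated by uniformly
#' permuting phenotype labels over the permutable cells with the graph held
#' fixed; all pairs share the same matched permutation stream. One-tailed
#' p-values use the +1 pseudo-count estimator
#' `p = (1 + #permutations at least as extreme) / (n_perm + 1)`, which never
#' returns 0 and is valid (super-uniform) under the null. Verdicts at `alpha`:
#' interaction if `p_high < alpha`, avoidance if `p_low < alpha`.
#'
#' The study's two analysis modes map to `permutable`: all cells (the
#' 29-cluster Histocat-style run) or immune cells only (the immune-focused
#' run); non-permutable cells keep their labels and still occupy graph
#' positions.
#'
#' @param graph a `neighbor_graph`.
#' @param labels phenotype labels parallel to `graph$cells`.
#' @param phenotypes phenotype set whose ordered pairs are enumerated
#'   (default: all labels observed). Cells labelled outside this set are
#'   never counted in a pair but still dilute the permutation null if
#'   permutable.
#' @param n_perm number of permutations (study settings: 99 or 5000).
#' @param alpha significance level for the verdicts (0.05 or 0.01).
#' @param permutable logical vector parallel to `graph$cells`; labels are
#'   shuffled only among these cells (default all).
#' @param seed integer seed.
#' @param roi_id identifier copied into the result rows.
#' @return data.frame, one row per ordered pair: `roi_id`, `pheno_a`,
#'   `pheno_b`, `n_a`, `n_b`, `observed_stat`, `p_high`, `p_low`, `verdict`
#'   (`interaction`, `avoidance`, `none`, or NA when a is absent).
#' @export
permutation_test <- function(graph, labels, phenotypes = NULL,
                             n_perm = 5000L, alpha = 0.01,
                             permutable = NULL, seed = 1L, roi_id = "roi") {
  stopifnot(length(labels) == length(graph$cells), n_perm >= 1)
  if (is.null(phenotypes)) phenotypes <- sort(unique(labels))
  if (is.null(permutable)) permutable <- rep(TRUE, length(labels))
  k <- length(phenotypes)
  lab <- match(labels, phenotypes)             # NA = outside the pair set
  n_of <- tabulate(lab, k)
  e <- graph$edges
  ia <- match(e[, 1], graph$cells); ib <- match(e[, 2], graph$cells)
  di <- c(ia, ib); dj <- c(ib, ia)             # directed edges
  tab_of <- function(l) {
    la <- l[di]; lb <- l[dj]
    ok <- !is.na(la) & !is.na(lb)
    tabulate((la[ok] - 1L) * k + lb[ok], k * k)
  }
  obs <- tab_of(lab)
  ge <- integer(k * k); le <- integer(k * k)
  set.seed(seed)
  widx <- which(permutable)
  for (p in seq_len(n_perm)) {
    l <- lab
    l[widx] <- lab[widx][sample.int(length(widx))]
    tp <- tab_of(l)
    ge <- ge + (tp >= obs)
    le <- le + (tp <= obs)
  }
  p_high <- (1 + ge) / (n_perm + 1)
  p_low <- (1 + le) / (n_perm + 1)
  grid <- expand.grid(a = seq_len(k), b = seq_len(k))
  idx <- (grid$a - 1L) * k + grid$b
  stat <- obs[idx] / n_of[grid$a]
  res <- data.frame(
    roi_id = roi_id,
    pheno_a = phenotypes[grid$a], pheno_b = phenotypes[grid$b],
    n_a = n_of[grid$a], n_b = n_of[grid$b],
    observed_stat = ifelse(n_of[grid$a] > 0, stat, NA_real_),
    p_high = p_high[idx], p_low = p_low[idx])
  res$verdict <- ifelse(is.na(res$observed_stat), NA_character_,
                 ifelse(res$p_high < alpha, "interaction",
                 ifelse(res$p_low < alpha, "avoidance", "none")))
  res
}

#' Exhaustive-enumeration neighborhood test (oracle)
#'
#' Exact version of [permutation_test()] that enumerates every distinct
#' permutation of the labels (all n! relabellings, so only feasible for tiny
#' ROIs). p-values are exact tail probabilities including the observed
#' labelling. Used to validate the Monte-Carlo estimator.
#'
#' @inheritParams permutation_test
#' @return data.frame as [permutation_test()] but with exact `p_high`,
#'   `p_low`.
#' @export
enumeration_test <- function(graph, labels, phenotypes = NULL, alpha = 0.01,
                             roi_id = "roi") {
  n <- length(graph$cells)
  stopifnot(n <= 8)                            # 8! = 40320 relabellings
  if (is.null(phenotypes)) phenotypes <- sort(unique(labels))
  k <- length(phenotypes)
  lab <- match(labels, phenotypes)
  e <- graph$edges
  ia <- match(e[, 1], graph$cells); ib <- match(e[, 2], graph$cells)
  di <- c(ia, ib); dj <- c(ib, ia)
  tab_of <- function(l) {
    la <- l[di]; lb <- l[dj]
    ok <- !is.na(la) & !is.na(lb)
    tabulate((la[ok] - 1L) * k + lb[ok], k * k)
  }
  obs <- tab_of(lab)
  perms <- all_permutations(n)
  ge <- integer(k * k); le <- integer(k * k)
  for (r in seq_len(nrow(perms))) {
    tp <- tab_of(lab[perms[r, ]])
    ge <- ge + (tp >= obs)
    le <- le + (tp <= obs)
  }
  m <- nrow(perms)
  n_of <- tabulate(lab, k)
  grid <- expand.grid(a = seq_len(k), b = seq_len(k))
  idx <- (grid$a - 1L) * k + grid$b
  res <- data.frame(
    roi_id = roi_id,
    pheno_a = phenotypes[grid$a], pheno_b = phenotypes[grid$b],
    n_a = n_of[grid$a], n_b = n_of[grid$b],
    observed_stat = ifelse(n_of[grid$a] > 0, obs[idx] / n_of[grid$a],
                           NA_real_),
    p_high = ge[idx] / m, p_low = le[idx] / m)
  res$verdict <- ifelse(is.na(res$observed_stat), NA_character_,
                 ifelse(res$p_high < alpha, "interaction",
                 ifelse(res$p_low < alpha, "avoidance", "none")))
  res
}

# internal: all permutations of 1..n as rows (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}

#' Signed cohort aggregation of neighborhood verdicts
#'
#' Per ordered pair, the percentage of ROIs with a significant interaction
#' minus the percentage with a significant avoidance, over the ROIs in which
#' the pair was testable (phenotype a present) -- so one interaction and one
#' avoidance cancel. Values are in [-100, 100]; pairs testable in no ROI are
#' NA.
#'
#' @param results row-bound [permutation_test()] results across ROIs.
#' @param alpha significance level at which verdicts are (re)computed from
#'   the stored p-values.
#' @return data.frame: `pheno_a`, `pheno_b`, `n_testable`, `n_interaction`,
#'   `n_avoidance`, `score_pct`.
#' @export
summarize_cohort <- function(results, alpha = 0.01) {
  testable <- !is.na(results$observed_stat)
  inter <- testable & results$p_high < alpha
  avoid <- testable & !inter & results$p_low < alpha
  key <- interaction(results$pheno_a, results$pheno_b, sep = "\r", drop = FALSE)
  agg <- data.frame(
    pair = levels(key),
    n_testable = as.integer(tapply(testable, key, sum)),
    n_interaction = as.integer(tapply(inter, key, sum)),
    n_avoidance = as.integer(tapply(avoid, key, sum)))
  parts <- strsplit(agg$pair, "\r", fixed = TRUE)
  out <- data.frame(
    pheno_a = vapply(parts, `[`, character(1), 1),
    pheno_b = vapply(parts, `[`, character(1), 2),
    n_testable = agg$n_testable,
    n_interaction = agg$n_interaction,
    n_avoidance = agg$n_avoidance)
  out$score_pct <- ifelse(out$n_testable > 0,
                          100 * (out$n_interaction - out$n_avoidance) /
                            out$n_testable, NA_real_)
  out[order(out$pheno_a, out$pheno_b), ]
}

#' Enumerate ordered phenotype pairs
#'
#' The hypothesis space of the pairwise neighborhood analysis: all ordered
#' pairs (including self-pairs) of the given phenotypes -- 121 for the 11
#' immune subpopulations.
#'
#' @param phenotypes character vector.
#' @return data.frame with columns `pheno_a`, `pheno_b`.
#' @export
enumerate_pairs <- function(phenotypes) {
  g <- expand.grid(pheno_a = phenotypes, pheno_b = phenotypes,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[order(g$pheno_a, g$pheno_b), , drop = FALSE]
}
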