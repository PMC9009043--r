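# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# one desk-scale CR ROI with the default planted interaction
fix_cr_sim <- function() fixture("cr_sim", function()
  simulate_roi(tissue_sim_config("CR", seed = 11)))

# one desk-scale NR ROI
fix_nr_sim <- function() fixture("nr_sim", function()
  simulate_roi(tissue_sim_config("NR", seed = 3)))

# balanced-mix cohort measured on ground-truth masks: clustering fixture
# (>= 300 cells per phenotype across 10 ROIs)
fix_balanced_cells <- function() fixture("balanced_cells", function() {
  mix <- stats::setNames(rep(1 / 11, 11), names(default_mix("NR")))
  cells <- list(); lab <- list()
  for (i in 1:10) {
    cfg <- tissue_sim_config("NR", n_immune = 330, n_nonimmune = 60,
                             phenotype_mix = mix, seed = 100 + i)
    sim <- simulate_roi(cfg)
    tab <- measure_cells(sim$truth$true_mask, sim$roi,
                         roi_id = paste0("R", i))
    cells[[i]] <- tab
    lab[[i]] <- sim$truth$phenotype_of_cell[tab$cell_id]
  }
  list(cells = do.call(rbind, cells), truth = unlist(lab))
})

# hand-built mask of disk cells at given centres/radii
make_disk_mask <- function(centers, radii, nr, nc) {
  m <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centers))) {
    for (dr in -ceiling(radii[i]):ceiling(radii[i]))
      for (dc in -ceiling(radii[i]):ceiling(radii[i]))
        if (dr^2 + dc^2 <= radii[i]^2) {
          r <- centers[i, 1] + dr; c <- centers[i, 2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc) m[r, c] <- i
        }
  }
  m
}

# brute-force neighbor pairs: minimum pairwise pixel distance <= radius
brute_force_neighbors <- function(mask, radius) {
  labs <- sort(unique(mask[mask > 0L]))
  px <- lapply(labs, function(l) which(mask == l, arr.ind = TRUE))
  out <- NULL
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    a <- px[[i]]; b <- px[[j]]
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    if (min(d2) <= radius^2)
      out <- rbind(out, c(labs[i], labs[j]))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# two columns with an exact sample correlation rho (closed-form PCA oracle)
make_exact_corr <- function(n, rho, seed = 1) {
  set.seed(seed)
  a <- scale(rnorm(n))[, 1]
  b <- stats::residuals(stats::lm(rnorm(n) ~ a))
  a <- a / stats::sd(a); b <- b / stats::sd(b)
  cbind(v1 = a, v2 = rho * a + sqrt(1 - rho^2) * b)
}

# adjusted Rand index between two labelings (closed form on the
# contingency table) -- kept independent of any clustering code
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
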