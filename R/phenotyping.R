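# internal: exact k-nearest neighbors (Euclidean), computed in row blocks so
# the full n x n distance matrix is never materialized
exact_knn <- function(x, k, block = 512L) {
  n <- nrow(x)
  rs <- rowSums(x^2)
  nn <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rs[s:e], rs, "+") - 2 * tcrossprod(x[s:e, , drop = FALSE], x)
    for (i in seq_len(e - s + 1L)) {
      d <- d2[i, ]
      d[s + i - 1L] <- Inf                       # never own neighbor
      nn[s + i - 1L, ] <- order(d)[seq_len(k)]
    }
  }
  nn
}

#' Phenograph-style meta-clustering
#'
#' Builds the exact k-nearest-neighbor graph over per-cell marker
#' intensities (raw, untransformed), reweights candidate edges by the Jaccard
#' overlap of the two cells' neighbor sets, drops zero-overlap edges, and
#' partitions the graph by seeded Louvain modularity maximization. Cluster
#' ids are ordered by decreasing size.
#'
#' @param cells cell table.
#' @param markers marker columns to cluster on (all panel markers by
#'   default usage).
#' @param k neighborhood size (study default 75). If fewer than `k + 1`
#'   cells are present, `k` is lowered to `n - 1` with a warning.
#' @param seed integer seed.
#' @return a `cluster_assignment`: list with `cluster` (per-cell id, 1 = the
#'   largest), `sizes`, `modularity`, `k`, `seed`.
#' @export
phenograph_cluster <- function(cells, markers, k = 75L, seed = 1L) {
  if (k < 1) imc_stop("k must be >= 1", "imc_config_error")
  x <- as.matrix(cells[, markers, drop = FALSE])
  if (!all(is.finite(x)))
    imc_stop("non-finite marker values", "imc_value_error")
  n <- nrow(x)
  if (n < k + 1L) {
    warning(sprintf("only %d cells; lowering k from %d to %d", n, k, n - 1L))
    k <- n - 1L
  }
  nn <- exact_knn(x, k)
  # candidate edges: union of directed kNN edges, undirected
  ii <- rep(seq_len(n), k)
  ed <- cbind(pmin(ii, as.integer(nn)), pmax(ii, as.integer(nn)))
  ed <- unique(ed)
  # Jaccard overlap of neighbor sets via sparse cross-product
  a <- Matrix::sparseMatrix(i = ii, j = as.integer(nn), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  s <- shared[ed]
  w <- s / (2 * k - s)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(ed[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  mem <- as.integer(igraph::membership(cl))
  # order clusters by decreasing size; break size ties by first appearance
  tab <- table(mem)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  remap <- integer(length(tab))
  remap[as.integer(names(tab))[ord]] <- seq_along(ord)
  mem <- remap[mem]
  structure(list(cluster = mem,
                 sizes = as.integer(table(factor(mem, seq_len(max(mem))))),
                 modularity = igraph::modularity(g, mem,
                                                 weights = igraph::E(g)$weight),
                 k = k, seed = seed),
            class = "cluster_assignment")
}

#' tSNE embedding of single cells
#'
#' Exact-gradient t-distributed stochastic neighbor embedding of per-cell
#' marker intensities, seeded and deterministic. The `theta` (Barnes-Hut
#' approximation) and `initial_dims` (a PCA cap applied by cytometry GUIs
#' before tSNE) arguments are recorded in the result's attributes for
#' provenance; with <= 110 markers the cap is a no-op, and the exact gradient
#' equals the theta -> 0 limit, appropriate at this data scale.
#'
#' @param cells cell table.
#' @param markers marker columns to embed.
#' @param perplexity target perplexity (default 30); lowered with a warning
#'   when `n <= 3 * perplexity`.
#' @param theta recorded Barnes-Hut parameter (default 0.5; inert).
#' @param initial_dims recorded PCA cap (default 110; inert for this panel).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed.
#' @return n x 2 coordinate matrix with attributes `perplexity`, `theta`,
#'   `initial_dims`.
#' @export
tsne_embed <- function(cells, markers, perplexity = 30, theta = 0.5,
                       initial_dims = 110L, n_iter = 500L, seed = 1L) {
  x <- as.matrix(cells[, markers, drop = FALSE])
  if (!all(is.finite(x)))
    imc_stop("non-finite marker values", "imc_value_error")
  n <- nrow(x)
  if (n <= 3 * perplexity + 1) {
    perplexity <- max(2, floor((n - 2) / 3))
    warning(sprintf("perplexity lowered to %g for n = %d", perplexity, n))
  }
  d2 <- as.matrix(stats::dist(x))^2
  p <- tsne_input_probs(d2, perplexity)
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    exagg <- if (it <= 100) 12 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    rs <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(rs, rs, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (exagg * p - q) * num
    grad <- 4 * (rowSums(l) * y - l %*% y)
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8),
                  0.01)
    inc <- mom * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  attr(y, "perplexity") <- perplexity
  attr(y, "theta") <- theta
  attr(y, "initial_dims") <- initial_dims
  y
}

# internal: symmetric tSNE input probabilities at a target perplexity,
# conditional precisions found by bisection
tsne_input_probs <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      h <- if (sw > 0) log(sw) + beta * sum(di * w) / sw else -Inf
      if (is.finite(h) && abs(h - target) < 1e-7) break
      if (h > target) {                          # entropy too high: sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    w <- exp(-di * beta)
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' Cluster-by-marker median profiles
#'
#' Entry (c, m) is the median over cells of cluster c of the per-cell mean
#' intensity of marker m; the companion z matrix is the column-standardized
#' (per marker, across clusters, population SD) version used for the
#' annotation heatmap. Zero-variance columns standardize to 0.
#'
#' @param cells cell table.
#' @param assignment a `cluster_assignment`.
#' @param markers marker columns to profile.
#' @return a `cluster_profile`: list with `medians` and `z`
#'   (clusters x markers matrices, rows named by cluster id).
#' @export
profile_clusters <- function(cells, assignment, markers) {
  cl <- assignment$cluster
  ks <- sort(unique(cl))
  med <- t(vapply(ks, function(k)
    apply(cells[cl == k, markers, drop = FALSE], 2L, stats::median),
    numeric(length(markers))))
  dimnames(med) <- list(ks, markers)
  structure(list(medians = med, z = zscore_columns(med)),
            class = "cluster_profile")
}

# single-marker identity rules, in evaluation order; CTL and the T-cell rule
# are handled separately because they need marker combinations
.solitary_rules <- c(CD20 = "B-cell", CD68 = "Macrophage", CD45RA = "Naive T-cell",
                     CD66a = "Neutrophil", HLADR = "HLADR+",
                     CD45 = "Other Leukocyte")
.numbered_families <- c("CTL", "Macrophage", "Other T-cell")

#' Annotate immune meta-clusters
#'
#' A cluster is immune iff its standardized median exceeds `z_threshold` for
#' at least one immune-role marker. The call standardizes `log1p` medians
#' (per marker, across clusters, population SD): graph clustering on raw
#' intensities routinely splits one marker-positive population into several
#' clusters of different brightness, and on the raw scale such splits dilute
#' the column SD until a genuinely positive cluster drops below any fixed
#' threshold; on the log scale positivity is an order-of-magnitude property
#' and survives intensity splits. The heatmap z matrix in the
#' `cluster_profile` stays on the raw scale.
#'
#' Immune clusters are then named by their dominant marker pattern
#' (positivity at `label_z` on the same standardized scale): CD20 B-cell;
#' CD68 Macrophage; CD3 with CD8 CTL; CD3 without CD8 Other T-cell; CD45RA
#' Naive T-cell; CD66a Neutrophil; HLADR HLADR+; CD45 alone Other Leukocyte.
#' Families that the study splits on intensity (CTL, Macrophage, Other
#' T-cell) are always numbered -1, -2, ... by decreasing size, as are any
#' other duplicated labels. Non-immune clusters collapse to the single label
#' `"not immune cell"`.
#'
#' @param profile a `cluster_profile`.
#' @param assignment the matching `cluster_assignment`.
#' @param panel the marker panel (immune roles define the candidate markers).
#' @param z_threshold immune-call threshold on the max immune-marker z
#'   (default 1).
#' @param label_z per-marker positivity threshold used only for naming
#'   (default 0.5).
#' @return the assignment, augmented with per-cluster `immune` and
#'   `phenotype` vectors and a per-cell `cell_phenotype`.
#' @export
annotate_immune <- function(profile, assignment, panel = default_panel(),
                            z_threshold = 1.0, label_z = 0.5) {
  im <- intersect(immune_markers(panel), colnames(profile$z))
  if (!length(im))
    imc_stop("panel has no immune-role markers among the profiled columns",
             "imc_config_error")
  z <- zscore_columns(log1p(profile$medians))
  dimnames(z) <- dimnames(profile$medians)
  ks <- as.integer(rownames(z))
  immune <- apply(z[, im, drop = FALSE], 1L, max) >= z_threshold
  pos <- z[, im, drop = FALSE] >= label_z
  has <- function(k, m) m %in% im && pos[k, m]
  base <- character(length(ks))
  for (k in seq_along(ks)) {
    if (!immune[k]) { base[k] <- "not immune cell"; next }
    base[k] <-
      if (has(k, "CD20")) "B-cell"
      else if (has(k, "CD68")) "Macrophage"
      else if (has(k, "CD3") && has(k, "CD8")) "CTL"
      else if (has(k, "CD3")) "Other T-cell"
      else if (has(k, "CD45RA")) "Naive T-cell"
      else if (has(k, "CD66a")) "Neutrophil"
      else if (has(k, "HLADR")) "HLADR+"
      else if (has(k, "CD45")) "Other Leukocyte"
      else {
        top <- im[which.max(z[k, im])]
        nm <- .solitary_rules[top]
        if (is.na(nm)) "Other Leukocyte" else unname(nm)
      }
  }
  sizes <- assignment$sizes[ks]
  label <- base
  for (b in unique(base[immune])) {
    idx <- which(base == b)
    if (b %in% .numbered_families || length(idx) > 1L) {
      ord <- idx[order(-sizes[idx], ks[idx])]
      label[ord] <- paste0(b, "-", seq_along(ord))
    }
  }
  assignment$cluster_ids <- ks
  assignment$immune <- stats::setNames(immune, ks)
  assignment$phenotype <- stats::setNames(label, ks)
  assignment$cell_phenotype <- label[match(assignment$cluster, ks)]
  assignment
}
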