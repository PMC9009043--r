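#' Segmentation parameters
#'
#' Defaults follow the common IMC convention: hot pixels are values exceeding
#' 5x the 3x3 neighborhood median; segmentation operates on the 2x-upscaled
#' grid, where nuclei need a probability >= 0.5, at least 4 px area and
#' watershed seeds >= 3 px apart, and cells are nuclei expanded by up to 5 px
#' through non-background pixels. All distances are in pixels of the grid the
#' step runs on (2x for segmentation, 1x for measurement).
#'
#' @param hotpixel_factor multiplier over the local median that defines a hot
#'   pixel.
#' @param nuclear_prob_threshold nuclear-plane threshold.
#' @param min_nucleus_area_px minimum nucleus area at 2x.
#' @param watershed_min_seed_distance_px minimum seed separation at 2x.
#' @param max_expansion_px maximum outward cell expansion at 2x.
#' @param watershed_tolerance intensity tolerance of the watershed split.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(hotpixel_factor = 5.0,
                                nuclear_prob_threshold = 0.5,
                                min_nucleus_area_px = 4L,
                                watershed_min_seed_distance_px = 3L,
                                max_expansion_px = 5L,
                                watershed_tolerance = 1) {
  p <- list(hotpixel_factor = hotpixel_factor,
            nuclear_prob_threshold = nuclear_prob_threshold,
            min_nucleus_area_px = min_nucleus_area_px,
            watershed_min_seed_distance_px = watershed_min_seed_distance_px,
            max_expansion_px = max_expansion_px,
            watershed_tolerance = watershed_tolerance)
  if (any(unlist(p) <= 0))
    imc_stop("all segmentation parameters must be positive",
             "imc_config_error")
  structure(p, class = "segmentation_params")
}

# internal: shift a matrix by (dy, dx), filling vacated cells
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs, cs] <- m[rs - dy, cs - dx, drop = FALSE]
  out
}

# internal: exact rowwise median of a 9-column matrix (5th smallest), via
# counting comparisons -- the vectorized form is much faster than apply()
row_median9 <- function(x) {
  n <- nrow(x)
  cnt <- matrix(0L, n, 9L)
  for (j in 1:9) for (k in 1:9) cnt[, j] <- cnt[, j] + (x[, k] <= x[, j])
  med <- rep(Inf, n)
  for (j in 1:9) {
    ok <- cnt[, j] >= 5L & x[, j] < med
    med[ok] <- x[ok, j]
  }
  med
}

#' Remove detector hot pixels
#'
#' Replaces any pixel whose value exceeds `factor` times the median of its
#' 3x3 neighborhood (edges replicated) by that median; all other pixels are
#' unchanged. Applied independently per channel.
#'
#' @param stack a `roi_image`, a channels x rows x cols array, or a matrix.
#' @param factor multiplier (> 1).
#' @return same type as the input.
#' @export
remove_hot_pixels <- function(stack, factor = 5.0) {
  if (factor <= 1) imc_stop("hot-pixel factor must be > 1", "imc_config_error")
  if (inherits(stack, "roi_image")) {
    stack$stack <- remove_hot_pixels(stack$stack, factor)
    return(stack)
  }
  if (is.matrix(stack)) {
    nr <- nrow(stack); nc <- ncol(stack)
    neigh <- matrix(0, nr * nc, 9L)
    j <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      j <- j + 1L
      # replicate edges: clamp source indices
      rs <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      neigh[, j] <- stack[rs, cs]
    }
    med <- matrix(row_median9(neigh), nr, nc)
    hot <- stack > factor * med
    stack[hot] <- med[hot]
    return(stack)
  }
  for (i in seq_len(dim(stack)[1]))
    stack[i, , ] <- remove_hot_pixels(matrix(stack[i, , ], dim(stack)[2],
                                             dim(stack)[3]), factor)
  stack
}

#' Bilinear 2x upscaling / label-preserving 1x downscaling
#'
#' `upscale2x` doubles both spatial dimensions of an intensity stack with
#' bilinear interpolation. `downscale_mask` brings a 2x label mask back to 1x
#' by taking the label of each 2x2 block's top-left pixel (nearest neighbor),
#' preserving label identity; odd trailing rows/columns are dropped.
#'
#' @param stack matrix, channels x rows x cols array, or `roi_image`.
#' @export
upscale2x <- function(stack) {
  if (inherits(stack, "roi_image")) {
    stack$stack <- upscale2x(stack$stack)
    stack$pixel_size_um <- stack$pixel_size_um / 2
    return(stack)
  }
  if (is.matrix(stack)) {
    m <- EBImage::resize(stack, w = 2L * nrow(stack), h = 2L * ncol(stack),
                         filter = "bilinear")
    return(matrix(as.numeric(m), 2L * nrow(stack), 2L * ncol(stack)))
  }
  d <- dim(stack)
  out <- array(0, c(d[1], 2L * d[2], 2L * d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- upscale2x(matrix(stack[i, , ], d[2], d[3]))
  out
}

#' @rdname upscale2x
#' @param mask2x integer label matrix on the 2x grid.
#' @export
downscale_mask <- function(mask2x) {
  m <- mask2x[seq(1L, 2L * (nrow(mask2x) %/% 2L), by = 2L),
              seq(1L, 2L * (ncol(mask2x) %/% 2L), by = 2L), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# internal: multiscale per-channel pixel features (Gaussian smoothings at
# sigma 1/2/4, gradient magnitude and Laplacian of the sigma-1 smoothing);
# returns an npix x nfeature matrix
pixel_features <- function(stack) {
  if (inherits(stack, "roi_image")) stack <- stack$stack
  d <- dim(stack)
  feats <- vector("list", d[1] * 5L)
  k <- 0L
  for (i in seq_len(d[1])) {
    ch <- matrix(stack[i, , ], d[2], d[3])
    g1 <- as.matrix(EBImage::gblur(ch, sigma = 1))
    g2 <- as.matrix(EBImage::gblur(ch, sigma = 2))
    g4 <- as.matrix(EBImage::gblur(ch, sigma = 4))
    gy <- (shift_mat(g1, -1, 0, 0) - shift_mat(g1, 1, 0, 0)) / 2
    gx <- (shift_mat(g1, 0, -1, 0) - shift_mat(g1, 0, 1, 0)) / 2
    grad <- sqrt(gx^2 + gy^2)
    lap <- shift_mat(g1, 1, 0) + shift_mat(g1, -1, 0) +
      shift_mat(g1, 0, 1) + shift_mat(g1, 0, -1) - 4 * g1
    for (f in list(g1, g2, g4, grad, lap)) {
      k <- k + 1L
      feats[[k]] <- as.numeric(f)
    }
  }
  out <- do.call(cbind, feats)
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

#' Train the three-class pixel classifier
#'
#' Supervised stand-in for interactive pixel-classification training: learns
#' nuclear / cytoplasm-membrane / background posteriors from sparse label
#' images over 2x-upscaled stacks, using multiscale per-channel features
#' (Gaussian smoothings at sigma 1, 2, 4, gradient magnitude, Laplacian) and
#' a seeded random forest.
#'
#' @param stacks list of channels x rows x cols arrays (2x grid) or
#'   `roi_image`s.
#' @param sparse_labels list of matching label matrices: 0 unlabeled,
#'   1 nuclear, 2 cytoplasm/membrane, 3 background. Every class must have at
#'   least one labeled pixel overall.
#' @param max_per_class training pixels subsampled per class.
#' @param ntree random-forest size.
#' @param seed integer seed; training is deterministic given it.
#' @return a `pixel_classifier` object.
#' @export
train_pixel_classifier <- function(stacks, sparse_labels,
                                   max_per_class = 3000L, ntree = 60L,
                                   seed = 1L) {
  if (!is.list(stacks)) stacks <- list(stacks)
  if (!is.list(sparse_labels)) sparse_labels <- list(sparse_labels)
  stopifnot(length(stacks) == length(sparse_labels))
  xs <- list(); ys <- list()
  for (i in seq_along(stacks)) {
    lab <- as.integer(sparse_labels[[i]])
    idx <- which(lab > 0L)
    if (!length(idx)) next
    f <- pixel_features(stacks[[i]])
    xs[[length(xs) + 1L]] <- f[idx, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[idx]
  }
  x <- do.call(rbind, xs); y <- unlist(ys)
  classes <- c("nuclear", "cytoplasm_membrane", "background")
  missing <- setdiff(1:3, unique(y))
  if (length(missing))
    imc_stop(sprintf("no labeled pixels for class: %s",
                     paste(classes[missing], collapse = ", ")),
             "imc_training_error")
  set.seed(seed)
  keep <- unlist(lapply(1:3, function(k) {
    i <- which(y == k)
    if (length(i) > max_per_class) sample(i, max_per_class) else i
  }))
  fit <- randomForest::randomForest(
    x = x[keep, , drop = FALSE],
    y = factor(classes[y[keep]], levels = classes), ntree = ntree)
  structure(list(model = fit, n_features = ncol(x), classes = classes,
                 seed = seed),
            class = "pixel_classifier")
}

#' Predict per-pixel class probabilities
#'
#' @param classifier a `pixel_classifier`.
#' @param stack2x a channels x rows x cols array or `roi_image` on the 2x
#'   grid, with the channel count the classifier was trained on.
#' @return `pixel_probabilities`: list of matrices `nuclear`,
#'   `cytoplasm_membrane`, `background`, summing to 1 at every pixel.
#' @export
predict_probabilities <- function(classifier, stack2x) {
  if (inherits(stack2x, "roi_image")) stack2x <- stack2x$stack
  f <- pixel_features(stack2x)
  if (ncol(f) != classifier$n_features)
    imc_stop(sprintf("classifier expects %d features (got %d): channel mismatch",
                     classifier$n_features, ncol(f)), "imc_format_error")
  pr <- stats::predict(classifier$model, f, type = "prob")
  d <- dim(stack2x)[2:3]
  structure(list(nuclear = matrix(pr[, "nuclear"], d[1], d[2]),
                 cytoplasm_membrane = matrix(pr[, "cytoplasm_membrane"],
                                             d[1], d[2]),
                 background = matrix(pr[, "background"], d[1], d[2])),
            class = "pixel_probabilities")
}

# internal: probability planes derived analytically from ground truth; used
# as the segmentation oracle in tests
truth_probabilities <- function(truth) {
  nuc <- (truth$nucleus_mask > 0) * 1
  cyto <- (truth$true_mask > 0 & truth$nucleus_mask == 0) * 1
  structure(list(nuclear = nuc, cytoplasm_membrane = cyto,
                 background = 1 - nuc - cyto),
            class = "pixel_probabilities")
}

#' Segment cells from pixel probabilities (2x grid)
#'
#' Nuclei are connected components of `nuclear >= threshold`, split by a
#' watershed on the distance transform (seed separation
#' `watershed_min_seed_distance_px`), with components below
#' `min_nucleus_area_px` removed. Cells are nuclei expanded outward by up to
#' `max_expansion_px` (Euclidean) through pixels where the background
#' probability is < 0.5; a pixel reachable from several nuclei goes to the
#' nearer one, ties to the lower label. Labels are compacted to 1..K.
#'
#' @param probs a `pixel_probabilities`.
#' @param params a [segmentation_params()].
#' @return integer label matrix on the 2x grid.
#' @export
segment_cells <- function(probs, params = segmentation_params()) {
  nucbin <- probs$nuclear >= params$nuclear_prob_threshold
  nr <- nrow(nucbin); nc <- ncol(nucbin)
  if (!any(nucbin)) return(matrix(0L, nr, nc))
  dm <- EBImage::distmap(nucbin * 1)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                           ext = params$watershed_min_seed_distance_px)
  lab <- matrix(as.integer(ws), nr, nc)
  # drop undersized nuclei, compact labels
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_nucleus_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  if (!any(lab > 0L)) return(matrix(0L, nr, nc))

  # expansion: nearest-nucleus-pixel assignment within max_expansion_px,
  # restricted to non-background pixels; offsets visited in increasing
  # Euclidean distance so the first assignment is the nearest, and
  # within a distance shell pmin() gives ties to the lower label
  allowed <- probs$background < 0.5
  res <- lab
  assigned <- lab > 0L
  r <- params$max_expansion_px
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off$d2 <- off$dy^2 + off$dx^2
  off <- off[off$d2 > 0 & off$d2 <= r^2, ]
  for (d2 in sort(unique(off$d2))) {
    sel <- off[off$d2 == d2, ]
    cand <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(sel))) {
      s <- shift_mat(lab, sel$dy[k], sel$dx[k], 0L)
      s[s == 0L] <- Inf
      cand <- pmin(cand, s)
    }
    new <- allowed & !assigned & is.finite(cand)
    res[new] <- as.integer(cand[new])
    assigned <- assigned | new
  }
  res
}

#' Per-cell measurements
#'
#' For every labeled cell: pixel area, centroid (mean pixel coordinates,
#' 0-based, pixel centers), and the mean intensity of each marker over the
#' cell's pixels at 1x. Intensities are the hot-pixel-filtered raw counts --
#' never transformed.
#'
#' @param mask integer label mask at 1x.
#' @param stack_1x `roi_image` or channels x rows x cols array at 1x.
#' @param panel the marker panel.
#' @param roi_id ROI identifier for the output rows.
#' @return cell-table data frame (see [write_cell_table()]).
#' @export
measure_cells <- function(mask, stack_1x, panel = NULL, roi_id = NULL) {
  if (inherits(stack_1x, "roi_image")) {
    if (is.null(panel)) panel <- stack_1x$panel
    if (is.null(roi_id)) roi_id <- stack_1x$roi_id
    stack_1x <- stack_1x$stack
  }
  if (is.null(roi_id)) roi_id <- "roi"
  if (!all(dim(mask) == dim(stack_1x)[2:3]))
    imc_stop("mask and stack dimensions differ", "imc_format_error")
  labs <- sort(unique(mask[mask > 0L]))
  empty <- data.frame(roi_id = character(0), cell_id = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area_px = integer(0))
  for (m in panel$marker) empty[[m]] <- numeric(0)
  if (!length(labs)) return(empty)
  idx <- which(mask > 0L)
  g <- factor(mask[idx], levels = labs)
  rows <- (idx - 1L) %% nrow(mask)          # 0-based coordinates
  cols <- (idx - 1L) %/% nrow(mask)
  area <- as.integer(table(g))
  out <- data.frame(
    roi_id = roi_id, cell_id = labs,
    centroid_row = as.numeric(tapply(rows, g, mean)),
    centroid_col = as.numeric(tapply(cols, g, mean)),
    area_px = area)
  for (i in seq_len(nrow(panel))) {
    ch <- matrix(stack_1x[i, , ], dim(stack_1x)[2], dim(stack_1x)[3])
    out[[panel$marker[i]]] <- as.numeric(rowsum(ch[idx], g)) / area
  }
  rownames(out) <- NULL
  out
}

#' Cell neighbor graph by mask dilation
#'
#' Cells a and b are neighbors iff some pixel of a lies within Euclidean
#' distance `radius_px` of some pixel of b (equivalently, the dilation of a
#' by a disk of that radius intersects b). The default radius of 4 px equals
#' 4 um at the acquisition resolution. Undirected, no self-pairs.
#'
#' @param mask integer label mask at 1x.
#' @param radius_px dilation radius (>= 1).
#' @return a `neighbor_graph`: list with `edges` (2-column matrix, a < b),
#'   and `cells` (sorted labels present in the mask).
#' @export
build_neighbor_graph <- function(mask, radius_px = 4) {
  if (radius_px < 1) imc_stop("radius must be >= 1", "imc_config_error")
  r <- ceiling(radius_px)
  pairs <- list()
  for (dy in 0:r) for (dx in -r:r) {
    if (dy == 0 && dx <= 0) next            # half-plane: each offset once
    if (dy^2 + dx^2 > radius_px^2) next
    s <- shift_mat(mask, dy, dx, 0L)
    sel <- mask > 0L & s > 0L & mask != s
    if (any(sel)) {
      a <- mask[sel]; b <- s[sel]
      pairs[[length(pairs) + 1L]] <- cbind(pmin(a, b), pmax(a, b))
    }
  }
  edges <- if (length(pairs)) unique(do.call(rbind, pairs))
           else matrix(integer(0), 0, 2)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("a", "b")
  structure(list(edges = edges, cells = sort(unique(mask[mask > 0L]))),
            class = "neighbor_graph")
}

#' Match predicted cells to ground truth
#'
#' One-to-one matching at an intersection-over-union floor: at IoU >= 0.5 a
#' match is necessarily unique in both directions. Reports the matched pairs
#' with their IoU and centroid error.
#'
#' @param true_mask,pred_mask label masks of the same shape.
#' @param min_iou IoU floor (default 0.5).
#' @return data.frame: `true_label`, `pred_label`, `iou`, `centroid_err_px`.
#' @export
match_cells <- function(true_mask, pred_mask, min_iou = 0.5) {
  sel <- true_mask > 0L | pred_mask > 0L
  t <- true_mask[sel]; p <- pred_mask[sel]
  inter <- table(t, p)
  inter <- inter[rownames(inter) != "0", colnames(inter) != "0", drop = FALSE]
  ta <- table(true_mask[true_mask > 0L])
  pa <- table(pred_mask[pred_mask > 0L])
  if (!length(inter)) return(data.frame(true_label = integer(0),
                                        pred_label = integer(0),
                                        iou = numeric(0),
                                        centroid_err_px = numeric(0)))
  ij <- which(inter > 0, arr.ind = TRUE)
  tl <- as.integer(rownames(inter))[ij[, 1]]
  pl <- as.integer(colnames(inter))[ij[, 2]]
  ov <- inter[ij]
  iou <- ov / (as.numeric(ta[as.character(tl)]) +
                 as.numeric(pa[as.character(pl)]) - ov)
  keep <- iou >= min_iou
  tl <- tl[keep]; pl <- pl[keep]; iou <- iou[keep]
  cen <- function(mask, labs) {
    idx <- which(mask > 0L)
    g <- factor(mask[idx], levels = labs)
    cbind(tapply((idx - 1L) %% nrow(mask), g, mean),
          tapply((idx - 1L) %/% nrow(mask), g, mean))
  }
  ct <- cen(true_mask, tl); cp <- cen(pred_mask, pl)
  data.frame(true_label = tl, pred_label = pl, iou = iou,
             centroid_err_px = sqrt(rowSums((ct - cp)^2)))
}

#' Segment one ROI end to end
#'
#' Hot-pixel filtering, 2x upscaling, pixel-probability prediction, watershed
#' segmentation, rescaling to 1x, and per-cell measurement on the filtered 1x
#' intensities.
#'
#' @param roi a `roi_image`.
#' @param classifier a trained `pixel_classifier`.
#' @param params a [segmentation_params()].
#' @return list: `mask` (1x label mask), `cells` (cell table), `probs`.
#' @export
segment_roi <- function(roi, classifier, params = segmentation_params()) {
  filt <- remove_hot_pixels(roi, params$hotpixel_factor)
  up <- upscale2x(filt$stack)
  probs <- predict_probabilities(classifier, up)
  mask2x <- segment_cells(probs, params)
  mask <- compact_labels(downscale_mask(mask2x))
  cells <- measure_cells(mask, filt)
  list(mask = mask, cells = cells, probs = probs)
}

#' Compact mask labels to 1..K
#'
#' @param mask integer label mask.
#' @return relabeled mask (order-preserving).
#' @export
compact_labels <- function(mask) {
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs)) return(mask)
  remap <- integer(max(labs))
  remap[labs] <- seq_along(labs)
  mask[mask > 0L] <- remap[mask[mask > 0L]]
  mask
}
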