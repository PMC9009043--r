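#' Tissue simulation configuration
#'
#' Builds the configuration for one simulated ROI. The defaults emulate the
#' two study conditions: `cohort = "NR"` (no rejection) produces sparse,
#' spatially isolated immune cells from a homogeneous point process over a
#' hepatocyte background, and `cohort = "CR"` (chronic rejection) produces
#' dense mixed immune aggregates with a planted Macrophage-2 / CTL-2 spatial
#' attraction. Cell densities follow the study's per-ROI immune cell counts
#' (~340 immune cells per 1 mm^2 NR ROI, ~1160 per CR ROI) scaled to the ROI
#' area; the desk-scale default is a 300 x 300 px ROI at 1 um/px, with the
#' full 1000 x 1000 px scale behind `scale = "full"`.
#'
#' @param cohort `"NR"` or `"CR"`.
#' @param roi_shape_px integer (rows, cols), each >= 64.
#' @param pixel_size_um physical scale (default 1).
#' @param n_nonimmune,n_immune cell counts; `NULL` uses cohort defaults.
#' @param phenotype_mix named probabilities over immune phenotypes (sums to 1);
#'   `NULL` uses cohort defaults.
#' @param aggregate_count,aggregate_sd_px number and Gaussian spread of immune
#'   aggregates (CR only); the default count scales with ROI area (~4 per
#'   desk-scale ROI).
#' @param planted_pairs list of `list(a =, b =, prob =)` pairwise attractions:
#'   a fraction `prob` of the b-phenotype cells is placed adjacent to an
#'   a-phenotype cell.
#' @param profiles phenotype profiles, see [default_profiles()].
#' @param background_rate Poisson background count rate per pixel per channel.
#' @param collagen_amp peak collagen band intensity (count rate).
#' @param hotpixel_rate fraction of pixels replaced by detector hot pixels.
#' @param noise_model `"lognormal-poisson"` (lognormal per-cell expression
#'   draw, then per-pixel Poisson shot noise) or `"poisson"` (no cell-to-cell
#'   variation).
#' @param scale `"desk"` (300 px) or `"full"` (1000 px); ignored when
#'   `roi_shape_px` is given explicitly.
#' @param seed integer seed.
#' @return a validated `tissue_sim_config` list.
#' @export
tissue_sim_config <- function(cohort = c("NR", "CR"),
                              roi_shape_px = NULL,
                              pixel_size_um = 1.0,
                              n_nonimmune = NULL,
                              n_immune = NULL,
                              phenotype_mix = NULL,
                              aggregate_count = NULL,
                              aggregate_sd_px = 25,
                              planted_pairs = NULL,
                              profiles = default_profiles(),
                              background_rate = 0.2,
                              collagen_amp = 4,
                              hotpixel_rate = 1e-4,
                              noise_model = c("lognormal-poisson", "poisson"),
                              scale = c("desk", "full"),
                              seed = 1L) {
  cohort <- match.arg(cohort)
  scale <- match.arg(scale)
  noise_model <- match.arg(noise_model)
  if (is.null(roi_shape_px))
    roi_shape_px <- if (scale == "full") c(1000L, 1000L) else c(300L, 300L)
  if (any(roi_shape_px < 64))
    imc_stop("roi dimensions must be >= 64 px", "imc_config_error")
  area_frac <- prod(roi_shape_px) / (300 * 300)
  if (is.null(n_nonimmune))
    n_nonimmune <- round(area_frac * if (cohort == "NR") 300 else 220)
  if (is.null(n_immune))
    n_immune <- round(area_frac * if (cohort == "NR") 40 else 200)
  if (is.null(phenotype_mix)) phenotype_mix <- default_mix(cohort)
  if (is.null(aggregate_count))                # ~4 aggregates per desk ROI
    aggregate_count <- max(2L, round(4 * area_frac))
  if (abs(sum(phenotype_mix) - 1) > 1e-9)
    imc_stop("phenotype_mix must sum to 1 within 1e-9", "imc_config_error")
  bad <- setdiff(names(phenotype_mix), names(profiles))
  if (length(bad))
    imc_stop(sprintf("phenotype_mix names unknown phenotypes: %s",
                     paste(bad, collapse = ", ")), "imc_config_error")
  if (is.null(planted_pairs) && cohort == "CR")
    planted_pairs <- list(list(a = "Macrophage-2", b = "CTL-2", prob = 0.8))
  if (is.null(planted_pairs)) planted_pairs <- list()
  for (pp in planted_pairs) {
    if (pp$prob < 0 || pp$prob > 1)
      imc_stop("planted adjacency prob must be in [0,1]", "imc_config_error")
    if (!all(c(pp$a, pp$b) %in% names(profiles)))
      imc_stop("planted pair names unknown phenotype", "imc_config_error")
  }
  structure(list(
    cohort = cohort, roi_shape_px = as.integer(roi_shape_px),
    pixel_size_um = pixel_size_um, n_nonimmune = n_nonimmune,
    n_immune = n_immune, phenotype_mix = phenotype_mix,
    aggregate_count = as.integer(aggregate_count),
    aggregate_sd_px = aggregate_sd_px, planted_pairs = planted_pairs,
    profiles = profiles, background_rate = background_rate,
    collagen_amp = collagen_amp, hotpixel_rate = hotpixel_rate,
    noise_model = noise_model, seed = as.integer(seed)
  ), class = "tissue_sim_config")
}

#' Default immune phenotype mixes per cohort
#'
#' NR is dominated by neutrophils and unspecified CD45+ leukocytes with no
#' Macrophage-1 (a population unique to rejection); CR is enriched for
#' Macrophage-2, CTL-2 and the two unspecified T-cell populations. The exact
#' proportions are the package's own choice (no per-phenotype abundance table
#' exists for the real cohorts); only these qualitative orderings matter to
#' downstream tests.
#'
#' @param cohort `"NR"` or `"CR"`.
#' @return named probability vector over the 11 immune phenotypes.
#' @export
default_mix <- function(cohort = c("NR", "CR")) {
  cohort <- match.arg(cohort)
  if (cohort == "NR")
    c("B-cell" = 0.05, "HLADR+" = 0.08, "Naive T-cell" = 0.10,
      "Other Leukocyte" = 0.22, "Neutrophil" = 0.22, "CTL-1" = 0.10,
      "CTL-2" = 0.03, "Macrophage-1" = 0.00, "Macrophage-2" = 0.02,
      "Other T-cell-1" = 0.09, "Other T-cell-2" = 0.09)
  else
    c("B-cell" = 0.05, "HLADR+" = 0.06, "Naive T-cell" = 0.06,
      "Other Leukocyte" = 0.06, "Neutrophil" = 0.04, "CTL-1" = 0.12,
      "CTL-2" = 0.18, "Macrophage-1" = 0.08, "Macrophage-2" = 0.15,
      "Other T-cell-1" = 0.10, "Other T-cell-2" = 0.10)
}

# internal: rasterize disk pixels; returns linear indices into a nr x nc matrix
disk_indices <- function(r0, c0, radius, nr, nc) {
  rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * nr + g$r[keep]
}

# internal: place cells by rejection sampling without overlap (>= 1 px gap).
# `positions` proposes candidate centers; returns n x 2 matrix or errors.
place_cells <- function(n, radii, propose, placed_r, placed_c, placed_rad,
                        max_tries = 8000L) {
  out_r <- numeric(n); out_c <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- propose(i)
      if (length(placed_r)) {
        d2 <- (placed_r - p[1])^2 + (placed_c - p[2])^2
        if (any(d2 <= (placed_rad + radii[i] + 1)^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      imc_stop(sprintf(
        "could not place cell %d of %d after %d tries: requested density too high",
        i, n, max_tries), "imc_simulation_error")
    out_r[i] <- p[1]; out_c[i] <- p[2]
    placed_r <- c(placed_r, p[1]); placed_c <- c(placed_c, p[2])
    placed_rad <- c(placed_rad, radii[i])
  }
  cbind(out_r, out_c)
}

#' Simulate one ROI with ground truth
#'
#' Places non-overlapping disk cells (radius ~ N(radius_px, 10%), clipped at
#' 2 px, with a >= 1 px gap so the true mask is an unambiguous segmentation
#' oracle), assigns immune phenotypes from the configured mix, renders each
#' channel as per-cell disk kernels scaled by a lognormal per-cell expression
#' draw plus Poisson shot noise, adds cell-independent collagen bands and
#' detector hot pixels, and returns both the image stack and the ground
#' truth. The nuclear channel is concentrated in an inner nuclear disk
#' (45% of the cell radius, floor 1.5 px) with a 15% cytoplasmic halo, which
#' is what makes the three pixel classes learnable. NR immune cells follow a
#' homogeneous point process; CR immune cells concentrate in
#' `aggregate_count` Gaussian blobs; for each planted pair (a, b, prob) a
#' fraction `prob` of b cells is placed with a 1-3 px boundary gap to a
#' random a cell. Deterministic given the config seed.
#'
#' @param config a [tissue_sim_config()].
#' @param panel the marker panel (defaults to [default_panel()]).
#' @return list with elements `roi` (a `roi_image`) and `truth` (list:
#'   `true_mask`, `nucleus_mask`, `phenotype_of_cell`, `cohort`,
#'   `planted_pairs`, `expression` (cell x marker lognormal draws),
#'   `centroids`, `radii`).
#' @export
simulate_roi <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "tissue_sim_config"))
  set.seed(config$seed)
  nr <- config$roi_shape_px[1]; nc <- config$roi_shape_px[2]
  profiles <- config$profiles
  nonim <- names(profiles)[!vapply(profiles, `[[`, logical(1), "immune")][1]

  # --- phenotype assignment -------------------------------------------------
  n_im <- config$n_immune; n_non <- config$n_nonimmune
  mix <- config$phenotype_mix
  pheno <- character(0)
  if (n_non > 0) pheno <- rep(nonim, n_non)
  if (n_im > 0)
    pheno <- c(pheno, sample(names(mix), n_im, replace = TRUE, prob = mix))
  n <- length(pheno)
  if (n == 0) {
    stack <- render_channels(config, panel, matrix(0L, nr, nc),
                             matrix(0L, nr, nc), NULL, character(0))
    return(list(
      roi = roi_image(stack, panel, roi_id = "roi", cohort = config$cohort,
                      pixel_size_um = config$pixel_size_um),
      truth = list(true_mask = matrix(0L, nr, nc),
                   nucleus_mask = matrix(0L, nr, nc),
                   phenotype_of_cell = character(0), cohort = config$cohort,
                   planted_pairs = config$planted_pairs,
                   expression = matrix(0, 0, nrow(panel),
                                       dimnames = list(NULL, panel$marker)),
                   centroids = matrix(0, 0, 2), radii = numeric(0))))
  }
  radii <- pmax(2, stats::rnorm(n, mean = vapply(
    profiles[pheno], `[[`, numeric(1), "radius_px"), sd = 0.1 *
      vapply(profiles[pheno], `[[`, numeric(1), "radius_px")))

  # planted b cells are placed last, next to an already-placed a cell
  planted_of <- rep(NA_integer_, n)    # index into planted_pairs
  for (k in seq_along(config$planted_pairs)) {
    pp <- config$planted_pairs[[k]]
    bi <- which(pheno == pp$b & is.na(planted_of))
    if (length(bi))
      planted_of[sample(bi, round(pp$prob * length(bi)))] <- k
  }
  free <- which(is.na(planted_of))
  dep <- which(!is.na(planted_of))

  # --- placement ------------------------------------------------------------
  margin <- radii + 1.5
  unif_prop <- function(i) c(stats::runif(1, margin[i], nr - margin[i]),
                             stats::runif(1, margin[i], nc - margin[i]))
  agg_centers <- cbind(stats::runif(config$aggregate_count, 0.15 * nr, 0.85 * nr),
                       stats::runif(config$aggregate_count, 0.15 * nc, 0.85 * nc))
  agg_prop <- function(i) {
    a <- sample.int(nrow(agg_centers), 1L)
    p <- agg_centers[a, ] + stats::rnorm(2, 0, config$aggregate_sd_px)
    pmin(pmax(p, margin[i]), c(nr, nc) - margin[i])
  }
  cen <- matrix(NA_real_, n, 2)
  # immune cells first (they are the constrained ones: CR aggregates and
  # planted adjacencies), then the space-filling non-immune background
  is_im <- pheno != nonim
  prop_for <- function(i) {
    if (is_im[i] && config$cohort == "CR") agg_prop(i) else unif_prop(i)
  }
  ord <- free[is_im[free]]
  placed <- place_cells(length(ord), radii[ord],
                        function(j) prop_for(ord[j]),
                        numeric(0), numeric(0), numeric(0))
  cen[ord, ] <- placed
  # planted cells: 1-3 px boundary gap to a random anchor of phenotype a
  for (i in dep) {
    pp <- config$planted_pairs[[planted_of[i]]]
    anchors <- which(pheno == pp$a & !is.na(cen[, 1]))
    prop <- if (length(anchors) == 0) {
      function(j) prop_for(i)
    } else {
      function(j) {
        a <- anchors[sample.int(length(anchors), 1L)]
        d <- radii[a] + radii[i] + stats::runif(1, 1, 3)
        th <- stats::runif(1, 0, 2 * pi)
        p <- cen[a, ] + d * c(cos(th), sin(th))
        pmin(pmax(p, margin[i]), c(nr, nc) - margin[i])
      }
    }
    done <- which(!is.na(cen[, 1]))
    cen[i, ] <- place_cells(1L, radii[i], prop,
                            cen[done, 1], cen[done, 2], radii[done])
  }
  # non-immune background cells fill the remaining space uniformly
  ordn <- free[!is_im[free]]
  if (length(ordn)) {
    done <- which(!is.na(cen[, 1]))
    cen[ordn, ] <- place_cells(length(ordn), radii[ordn],
                               function(j) unif_prop(ordn[j]),
                               cen[done, 1], cen[done, 2], radii[done])
  }

  # --- masks ----------------------------------------------------------------
  true_mask <- matrix(0L, nr, nc)
  nucleus_mask <- matrix(0L, nr, nc)
  nuc_r <- pmax(1.5, 0.45 * radii)
  for (i in seq_len(n)) {
    true_mask[disk_indices(cen[i, 1], cen[i, 2], radii[i], nr, nc)] <- i
    nucleus_mask[disk_indices(cen[i, 1], cen[i, 2], nuc_r[i], nr, nc)] <- i
  }

  stack_expr <- render_channels(config, panel, true_mask, nucleus_mask,
                                cen, pheno)
  truth <- list(true_mask = true_mask, nucleus_mask = nucleus_mask,
                phenotype_of_cell = pheno, cohort = config$cohort,
                planted_pairs = config$planted_pairs,
                expression = attr(stack_expr, "expression"),
                centroids = cen, radii = radii)
  attr(stack_expr, "expression") <- NULL
  roi <- roi_image(stack_expr, panel, roi_id = "roi", cohort = config$cohort,
                   pixel_size_um = config$pixel_size_um)
  list(roi = roi, truth = truth)
}

# internal: render the channel stack given masks and phenotypes; attaches the
# per-cell lognormal expression draws as attr "expression" (the measurement
# oracle). Consumes RNG, so call under the config seed.
render_channels <- function(config, panel, true_mask, nucleus_mask, cen,
                            pheno) {
  nr <- nrow(true_mask); nc <- ncol(true_mask)
  n <- length(pheno)
  profiles <- config$profiles
  markers <- panel$marker
  nucm <- nuclear_marker(panel)
  expr <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  if (n > 0) {
    means <- t(vapply(profiles[pheno], function(p) p$marker_means[markers],
                      numeric(length(markers))))
    cvs <- t(vapply(profiles[pheno], function(p) p$marker_cv[markers],
                    numeric(length(markers))))
    if (config$noise_model == "lognormal-poisson") {
      sdl <- sqrt(log(1 + cvs^2))
      pos <- means > 0
      expr[pos] <- stats::rlnorm(sum(pos),
                                 meanlog = log(means[pos]) - sdl[pos]^2 / 2,
                                 sdlog = sdl[pos])
    } else expr <- means
  }
  stack <- array(0, c(length(markers), nr, nc))
  cell_px <- if (n > 0) split(which(true_mask > 0), true_mask[true_mask > 0])
  nuc_px <- if (n > 0) split(which(nucleus_mask > 0),
                             nucleus_mask[nucleus_mask > 0])
  for (m in seq_along(markers)) {
    rate <- matrix(config$background_rate, nr, nc)
    if (markers[m] == "Collagen1" || panel$role[m] == "structural") {
      rate <- rate + collagen_field(nr, nc, config$collagen_amp)
    }
    if (n > 0) {
      if (markers[m] == nucm) {
        for (i in seq_len(n)) {
          px <- cell_px[[as.character(i)]]
          rate[px] <- rate[px] + 0.15 * expr[i, m]
          npx <- nuc_px[[as.character(i)]]
          rate[npx] <- rate[npx] + 0.85 * expr[i, m]
        }
      } else {
        for (i in seq_len(n)) {
          if (expr[i, m] <= 0) next
          px <- cell_px[[as.character(i)]]
          rate[px] <- rate[px] + expr[i, m]
        }
      }
    }
    counts <- matrix(stats::rpois(nr * nc, rate), nr, nc)
    # detector hot pixels: isolated spuriously high values
    if (config$hotpixel_rate > 0) {
      nhot <- stats::rbinom(1, nr * nc, config$hotpixel_rate)
      if (nhot > 0) {
        idx <- sample.int(nr * nc, nhot)
        counts[idx] <- counts[idx] + stats::rpois(nhot, 80)
      }
    }
    stack[m, , ] <- counts
  }
  attr(stack, "expression") <- expr
  stack
}

# internal: smooth cell-independent collagen bands in [0, amp]: a soft
# sinusoidal ridge field with random orientation and phase.
collagen_field <- function(nr, nc, amp) {
  if (amp <= 0) return(matrix(0, nr, nc))
  th <- stats::runif(1, 0, pi)
  wavelength <- stats::runif(1, 60, 120)
  phase <- stats::runif(1, 0, 2 * pi)
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- (r * cos(th) + c * sin(th)) * 2 * pi / wavelength + phase
  band <- pmax(0, sin(u))^3            # narrow soft ridges
  amp * band
}

#' Simulate a cohort of ROIs
#'
#' Per-ROI seeds are derived reproducibly from the master seed; NR ROIs use
#' the sparse configuration, CR ROIs the aggregate configuration. The default
#' cohort shape (8 NR / 24 CR) matches the study design of 32 ROIs.
#'
#' @param n_nr_roi,n_cr_roi ROI counts (>= 1).
#' @param seed master seed.
#' @param nr_config,cr_config optional base configs; their seed field is
#'   overwritten per ROI.
#' @param panel the marker panel.
#' @return list of `list(roi =, truth =)`, NR ROIs first; each ROI's `roi_id`
#'   is `"NR-i"` or `"CR-i"`.
#' @export
generate_cohort <- function(n_nr_roi = 8L, n_cr_roi = 24L, seed = 1L,
                            nr_config = NULL, cr_config = NULL,
                            panel = default_panel()) {
  if (n_nr_roi < 1 || n_cr_roi < 1)
    imc_stop("cohort needs at least one ROI per group", "imc_config_error")
  if (is.null(nr_config)) nr_config <- tissue_sim_config("NR")
  if (is.null(cr_config)) cr_config <- tissue_sim_config("CR")
  ids <- c(paste0("NR-", seq_len(n_nr_roi)), paste0("CR-", seq_len(n_cr_roi)))
  cfgs <- c(rep(list(nr_config), n_nr_roi), rep(list(cr_config), n_cr_roi))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cfg <- cfgs[[i]]
    cfg$seed <- derive_seed(seed, i)
    sim <- simulate_roi(cfg, panel)
    sim$roi$roi_id <- ids[i]
    out[[i]] <- sim
  }
  names(out) <- ids
  out
}

#' Simulate per-ROI median-marker features with a cohort shift
#'
#' Feature-level companion to the image simulator, used for calibration and
#' modeling-recovery experiments where only the per-ROI feature matrix
#' matters. Each ROI's median signal for marker m is
#' `baseline_m * exp(N(0, noise_sd))`, with CR ROIs multiplied by `shift` on
#' every immune marker (a planted global immune elevation, the qualitative
#' pattern of chronic rejection).
#'
#' @param n_nr,n_cr ROI counts.
#' @param shift CR fold change on immune markers (default 2; 1 = null).
#' @param noise_sd lognormal noise SD on the log scale.
#' @param panel the marker panel.
#' @param seed integer seed.
#' @return data.frame: `roi_id`, `cohort`, one column per immune marker.
#' @export
simulate_marker_features <- function(n_nr = 8L, n_cr = 24L, shift = 2,
                                     noise_sd = 0.4,
                                     panel = default_panel(), seed = 1L) {
  set.seed(seed)
  mk <- immune_markers(panel)
  baseline <- stats::setNames(c(2, 6, 3, 8, 4, 7, 6, 5)[seq_along(mk)], mk)
  n <- n_nr + n_cr
  cohort <- c(rep("NR", n_nr), rep("CR", n_cr))
  x <- matrix(stats::rlnorm(n * length(mk), meanlog = 0, sdlog = noise_sd),
              n, length(mk), dimnames = list(NULL, mk))
  x <- sweep(x, 2L, baseline, "*")
  x[cohort == "CR", ] <- x[cohort == "CR", ] * shift
  data.frame(roi_id = c(paste0("NR-", seq_len(n_nr)),
                        paste0("CR-", seq_len(n_cr))),
             cohort = cohort, x, check.names = FALSE)
}
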