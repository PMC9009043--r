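#' Nearest-neighbor 2x upscaling of a label mask
#'
#' Each 1x pixel becomes a 2x2 block with the same label (the inverse
#' convention of [downscale_mask()], whose top-left sampling makes
#' upscale-then-downscale the identity on labels).
#'
#' @param mask integer label matrix.
#' @return label matrix with doubled dimensions.
#' @export
upscale_mask2x <- function(mask) {
  m <- mask[rep(seq_len(nrow(mask)), each = 2L),
            rep(seq_len(ncol(mask)), each = 2L), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Sparse training labels from simulation ground truth
#'
#' Scripted stand-in for interactive brush labelling: samples a fixed number
#' of pixels per class (1 nuclear, 2 cytoplasm/membrane, 3 background) from
#' the ground-truth masks, on the 2x grid the classifier trains on.
#'
#' @param truth ground truth from [simulate_roi()].
#' @param n_per_class labelled pixels per class.
#' @param seed integer seed.
#' @return sparse label matrix (0 = unlabeled) on the 2x grid.
#' @export
training_labels_from_truth <- function(truth, n_per_class = 2000L, seed = 1L) {
  nuc <- upscale_mask2x(truth$nucleus_mask) > 0L
  cell <- upscale_mask2x(truth$true_mask) > 0L
  set.seed(seed)
  lab <- matrix(0L, nrow(nuc), ncol(nuc))
  pick <- function(idx) idx[sample.int(length(idx),
                                       min(n_per_class, length(idx)))]
  lab[pick(which(nuc))] <- 1L
  lab[pick(which(cell & !nuc))] <- 2L
  lab[pick(which(!cell))] <- 3L
  lab
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML run configuration (or takes a list), fills defaults, rejects
#' unknown keys, and cross-checks parameter ranges. The defaults are the
#' study settings: Phenograph k = 75, neighborhood radius 4 px, 5000
#' permutations at alpha 0.01.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "imcscope_run",
    seed = 1L,
    stages = c("simulate", "segment", "cluster", "quantify",
               "neighborhood", "model"),
    cohort = list(n_nr_roi = 2L, n_cr_roi = 2L, scale = "desk",
                  roi_px = NULL),
    segmentation = list(hotpixel_factor = 5, nuclear_prob_threshold = 0.5,
                        min_nucleus_area_px = 4L,
                        watershed_min_seed_distance_px = 3L,
                        max_expansion_px = 5L, n_training_per_class = 2000L),
    clustering = list(k = 75L, run_tsne = FALSE, tsne_perplexity = 30,
                      z_threshold = 1.0),
    neighborhood = list(radius_px = 4, n_perm = 5000L, alpha = 0.01,
                        mode = "immune"),
    modeling = list(scale = TRUE, cor_method = "spearman",
                    cor_threshold = 0.8)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    imc_stop(sprintf("unknown config keys: %s",
                     paste(unknown, collapse = ", ")), "imc_config_error")
  for (blk in names(config)) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]]))) {
      unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(unknown))
        imc_stop(sprintf("unknown config keys in '%s': %s", blk,
                         paste(unknown, collapse = ", ")), "imc_config_error")
      defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    } else defaults[[blk]] <- config[[blk]]
  }
  cfg <- defaults
  if (cfg$neighborhood$alpha <= 0 || cfg$neighborhood$alpha >= 1)
    imc_stop("alpha must be in (0, 1)", "imc_config_error")
  if (cfg$neighborhood$radius_px <= 0)
    imc_stop("radius must be > 0", "imc_config_error")
  if (cfg$clustering$k < 1) imc_stop("k must be >= 1", "imc_config_error")
  if (cfg$neighborhood$n_perm < 1)
    imc_stop("n_perm must be >= 1", "imc_config_error")
  bad <- setdiff(cfg$stages, c("simulate", "segment", "cluster", "quantify",
                               "neighborhood", "model"))
  if (length(bad))
    imc_stop(sprintf("unknown stages: %s", paste(bad, collapse = ", ")),
             "imc_config_error")
  class(cfg) <- "run_config"
  cfg
}

#' Write a normalized config back to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# internal: write a stage manifest (parameters, seed, output file hashes)
write_manifest <- function(dir, stage, params, seed, files) {
  files <- files[file.exists(files)]
  man <- list(stage = stage, params = params, seed = seed,
              outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes the enabled stages in order -- simulate, segment, cluster,
#' quantify, neighborhood, model -- writing every artifact (TIFF stacks and
#' masks, CSV tables, JSON manifests) under `out_dir`. All stage seeds derive
#' from the master seed, so a rerun with the same config reproduces identical
#' outputs. A stage failure stops the run with the failing stage named;
#' completed outputs are retained.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param panel the marker panel.
#' @return run report: list of completed stages with their key outputs.
#' @export
run_pipeline <- function(config = list(), panel = default_panel()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = character(0), out_dir = cfg$out_dir)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e)
      imc_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "imc_stage_error"))
    report$stages <<- c(report$stages, name)
    message(sprintf("[imcscope] stage %-12s done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  run_stage("simulate", function() {
    shape <- if (!is.null(cfg$cohort$roi_px))
      rep(as.integer(cfg$cohort$roi_px), 2L)
    sims <- generate_cohort(
      cfg$cohort$n_nr_roi, cfg$cohort$n_cr_roi,
      seed = derive_seed(cfg$seed, 1L),
      nr_config = tissue_sim_config("NR", scale = cfg$cohort$scale,
                                    roi_shape_px = shape),
      cr_config = tissue_sim_config("CR", scale = cfg$cohort$scale,
                                    roi_shape_px = shape),
      panel = panel)
    state$sims <- sims
    files <- character(0)
    ptab <- list()
    for (id in names(sims)) {
      f1 <- file.path(cfg$out_dir, paste0(id, "_stack.tiff"))
      f2 <- file.path(cfg$out_dir, paste0(id, "_true_mask.tiff"))
      write_roi(sims[[id]]$roi, f1)
      write_mask(sims[[id]]$truth$true_mask, f2)
      files <- c(files, f1, f2)
      tr <- sims[[id]]$truth
      if (length(tr$phenotype_of_cell))
        ptab[[id]] <- data.frame(roi_id = id,
                                 cell_id = seq_along(tr$phenotype_of_cell),
                                 phenotype = tr$phenotype_of_cell,
                                 cohort = tr$cohort)
    }
    f3 <- file.path(cfg$out_dir, "true_phenotypes.csv")
    data.table::fwrite(do.call(rbind, ptab), f3)
    write_manifest(cfg$out_dir, "simulate", cfg$cohort,
                   derive_seed(cfg$seed, 1L), c(files, f3))
  })

  run_stage("segment", function() {
    sims <- state$sims
    sp <- segmentation_params(
      hotpixel_factor = cfg$segmentation$hotpixel_factor,
      nuclear_prob_threshold = cfg$segmentation$nuclear_prob_threshold,
      min_nucleus_area_px = cfg$segmentation$min_nucleus_area_px,
      watershed_min_seed_distance_px = cfg$segmentation$watershed_min_seed_distance_px,
      max_expansion_px = cfg$segmentation$max_expansion_px)
    seed <- derive_seed(cfg$seed, 2L)
    first <- sims[[1]]
    labs <- training_labels_from_truth(first$truth,
                                       cfg$segmentation$n_training_per_class,
                                       seed = seed)
    clf <- train_pixel_classifier(
      upscale2x(remove_hot_pixels(first$roi, sp$hotpixel_factor)$stack),
      labs, seed = seed)
    tabs <- list(); files <- character(0)
    state$masks <- list()
    for (id in names(sims)) {
      seg <- segment_roi(sims[[id]]$roi, clf, sp)
      state$masks[[id]] <- seg$mask
      f <- file.path(cfg$out_dir, paste0(id, "_mask.tiff"))
      write_mask(seg$mask, f)
      files <- c(files, f)
      tabs[[id]] <- seg$cells
      message(sprintf("[imcscope]   %s: %d cells", id, nrow(seg$cells)))
    }
    state$cells <- do.call(rbind, tabs)
    f <- file.path(cfg$out_dir, "cells.csv")
    write_cell_table(state$cells, f, panel)
    write_manifest(cfg$out_dir, "segment", unclass(sp), seed, c(files, f))
  })

  run_stage("cluster", function() {
    seed <- derive_seed(cfg$seed, 3L)
    cells <- state$cells
    asg <- phenograph_cluster(cells, panel$marker, k = cfg$clustering$k,
                              seed = seed)
    prof <- profile_clusters(cells, asg, panel$marker)
    asg <- annotate_immune(prof, asg, panel,
                           z_threshold = cfg$clustering$z_threshold)
    state$assignment <- asg
    f1 <- file.path(cfg$out_dir, "cluster_assignment.csv")
    data.table::fwrite(data.frame(roi_id = cells$roi_id,
                                  cell_id = cells$cell_id,
                                  meta_cluster = asg$cluster,
                                  phenotype = asg$cell_phenotype), f1)
    f2 <- file.path(cfg$out_dir, "cluster_profile.csv")
    data.table::fwrite(data.frame(cluster = rownames(prof$medians),
                                  prof$medians, check.names = FALSE), f2)
    files <- c(f1, f2)
    if (isTRUE(cfg$clustering$run_tsne)) {
      y <- tsne_embed(cells, panel$marker,
                      perplexity = cfg$clustering$tsne_perplexity, seed = seed)
      f3 <- file.path(cfg$out_dir, "tsne.csv")
      data.table::fwrite(data.frame(roi_id = cells$roi_id,
                                    cell_id = cells$cell_id,
                                    tsne1 = y[, 1], tsne2 = y[, 2]), f3)
      files <- c(files, f3)
    }
    write_manifest(cfg$out_dir, "cluster", cfg$clustering, seed, files)
  })

  run_stage("quantify", function() {
    cells <- state$cells
    cohort_of <- vapply(state$sims, function(s) s$truth$cohort, character(1))
    med <- median_marker_per_roi(cells, panel$marker, cohort_of)
    props <- immune_proportions(cells, state$assignment$cell_phenotype,
                                cohort_of = cohort_of)
    zc <- standardize_counts(props$counts)
    cmp_m <- compare_cohorts(med, immune_markers(panel))
    f <- file.path(cfg$out_dir,
                   c("roi_median_markers.csv", "roi_immune_counts.csv",
                     "roi_immune_proportions.csv", "roi_count_zscores.csv",
                     "cohort_marker_tests.csv"))
    data.table::fwrite(med, f[1])
    data.table::fwrite(props$counts, f[2])
    data.table::fwrite(props$proportions, f[3])
    data.table::fwrite(data.frame(roi_id = rownames(zc), zc,
                                  check.names = FALSE), f[4])
    data.table::fwrite(cmp_m, f[5])
    state$median_markers <- med
    state$props <- props
    write_manifest(cfg$out_dir, "quantify", list(), cfg$seed, f)
  })

  run_stage("neighborhood", function() {
    seed <- derive_seed(cfg$seed, 5L)
    cells <- state$cells
    phen <- state$assignment$cell_phenotype
    imm_ph <- sort(unique(phen[phen != "not immune cell"]))
    res <- list()
    for (id in names(state$masks)) {
      g <- build_neighbor_graph(state$masks[[id]],
                                cfg$neighborhood$radius_px)
      sel <- cells$roi_id == id
      lab <- phen[sel][match(g$cells, cells$cell_id[sel])]
      permutable <- if (cfg$neighborhood$mode == "immune")
        lab != "not immune cell" else rep(TRUE, length(lab))
      res[[id]] <- permutation_test(
        g, lab, phenotypes = imm_ph, n_perm = cfg$neighborhood$n_perm,
        alpha = cfg$neighborhood$alpha, permutable = permutable,
        seed = derive_seed(seed, match(id, names(state$masks))), roi_id = id)
    }
    res <- do.call(rbind, res)
    summ <- summarize_cohort(res, cfg$neighborhood$alpha)
    f <- file.path(cfg$out_dir, c("neighborhood_results.csv",
                                  "neighborhood_summary.csv"))
    data.table::fwrite(res, f[1])
    data.table::fwrite(summ, f[2])
    write_manifest(cfg$out_dir, "neighborhood", cfg$neighborhood, seed, f)
  })

  run_stage("model", function() {
    med <- state$median_markers
    cnt <- state$props$counts
    x <- cbind(med[, c("roi_id", immune_markers(panel))],
               cnt[match(med$roi_id, cnt$roi_id),
                   !(names(cnt) %in% c("roi_id", "cohort")), drop = FALSE])
    num <- vapply(x, is.numeric, logical(1))
    flat <- num & vapply(x, function(v) is.numeric(v) && stats::sd(v) == 0,
                         logical(1))
    if (any(flat)) {
      message(sprintf("[imcscope]   dropping constant features: %s",
                      paste(names(x)[flat], collapse = ", ")))
      x <- x[, !flat, drop = FALSE]
    }
    pca <- pca_fit(x, scale = cfg$modeling$scale)
    test <- pc1_test(pca, med$cohort)
    lr <- logistic_pc1(pca, med$cohort)
    net <- correlation_network(x, method = cfg$modeling$cor_method,
                               threshold = cfg$modeling$cor_threshold)
    f <- file.path(cfg$out_dir, c("pca_scores.csv", "pca_contributions.csv",
                                  "network_edges.csv", "model_summary.json"))
    data.table::fwrite(data.frame(roi_id = med$roi_id, cohort = med$cohort,
                                  pca$scores, check.names = FALSE), f[1])
    data.table::fwrite(data.frame(variable = rownames(pca$contrib_pct),
                                  pca$contrib_pct, check.names = FALSE), f[2])
    data.table::fwrite(net, f[3])
    jsonlite::write_json(list(
      explained_var_pct = pca$explained_var_pct,
      pc1_wilcoxon_p = test$p,
      logistic = list(intercept = lr$intercept, slope = lr$slope,
                      ridge = lr$ridge, separation = lr$separation,
                      n_correct_ge_075 = lr$n_correct_ge_075,
                      n_outliers = lr$n_outliers, accuracy = lr$accuracy)),
      f[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(cfg$out_dir, "model", cfg$modeling, cfg$seed, f)
  })

  report
}
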