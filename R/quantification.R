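#' Per-ROI median marker signal
#'
#' The median, over all cells of an ROI (immune and not), of the per-cell
#' mean intensity of each marker. Even cell counts use the mean-of-middle-two
#' convention. ROIs with no cells are excluded with a warning.
#'
#' @param cells cell table (multiple ROIs allowed).
#' @param markers marker columns to summarize.
#' @param cohort_of optional named vector mapping roi_id to cohort.
#' @return data.frame: `roi_id`, optional `cohort`, one column per marker.
#' @export
median_marker_per_roi <- function(cells, markers, cohort_of = NULL) {
  rois <- unique(cells$roi_id)
  counts <- table(cells$roi_id)[rois]
  if (any(counts == 0)) {
    warning("excluding ROIs with no cells")
    rois <- rois[counts > 0]
  }
  out <- data.frame(roi_id = rois)
  if (!is.null(cohort_of)) out$cohort <- unname(cohort_of[rois])
  for (m in markers)
    out[[m]] <- vapply(rois, function(r)
      stats::median(cells[[m]][cells$roi_id == r]), numeric(1))
  rownames(out) <- NULL
  out
}

#' Immune subpopulation counts and proportions per ROI
#'
#' Counts cells of each immune phenotype per ROI and divides by the ROI's
#' total immune cell count (non-immune cells are excluded from the
#' denominator). ROIs with zero immune cells get missing proportions, not
#' zeros.
#'
#' @param cells cell table.
#' @param cell_phenotype per-cell phenotype labels (from [annotate_immune()]
#'   or ground truth); `"not immune cell"` marks non-immune cells.
#' @param phenotypes immune phenotype set defining the columns; defaults to
#'   the labels observed.
#' @param cohort_of optional named vector mapping roi_id to cohort.
#' @return list with `counts` and `proportions` data frames (one row per
#'   ROI) and `totals` (immune cells per ROI).
#' @export
immune_proportions <- function(cells, cell_phenotype, phenotypes = NULL,
                               cohort_of = NULL) {
  stopifnot(length(cell_phenotype) == nrow(cells))
  imm <- cell_phenotype != "not immune cell"
  if (is.null(phenotypes))
    phenotypes <- sort(unique(cell_phenotype[imm]))
  rois <- unique(cells$roi_id)
  tab <- table(factor(cells$roi_id[imm], rois),
               factor(cell_phenotype[imm], phenotypes))
  counts <- matrix(as.integer(tab), length(rois), length(phenotypes),
                   dimnames = list(rois, phenotypes))
  tot <- rowSums(counts)
  prop <- counts / ifelse(tot > 0, tot, NA_real_)
  wrap <- function(m) {
    d <- data.frame(roi_id = rois)
    if (!is.null(cohort_of)) d$cohort <- unname(cohort_of[rois])
    cbind(d, as.data.frame(m, check.names = FALSE))
  }
  list(counts = wrap(counts), proportions = wrap(prop),
       totals = stats::setNames(tot, rois))
}

#' Standardize subpopulation counts across ROIs
#'
#' Column z-scores (per subpopulation, across ROIs, population SD) of the
#' per-ROI count matrix; the zero point of each column is that
#' subpopulation's average frequency. Constant columns standardize to 0.
#'
#' @param counts per-ROI count data frame from [immune_proportions()] (or any
#'   numeric matrix with ROI rows).
#' @return z matrix with the same dimnames.
#' @export
standardize_counts <- function(counts) {
  num <- counts[, !(names(counts) %in% c("roi_id", "cohort")), drop = FALSE]
  m <- as.matrix(num)
  if (nrow(m) < 2)
    imc_stop("standardization needs at least 2 ROIs", "imc_config_error")
  z <- zscore_columns(m)
  rownames(z) <- if ("roi_id" %in% names(counts)) counts$roi_id
  z
}

#' Wilcoxon rank-sum cohort comparison
#'
#' Two-sided rank-sum test per variable between cohorts, with the exact null
#' distribution when both groups have <= 10 observations and no ties, and the
#' tie-corrected normal approximation otherwise. Raw p-values and
#' Benjamini-Hochberg q-values are reported side by side; the study's own
#' headline convention is the unadjusted p.
#'
#' @param features data.frame with a `cohort` column and numeric variable
#'   columns (e.g. from [median_marker_per_roi()]).
#' @param variables columns to test; defaults to all numeric columns.
#' @param groups the two cohort labels to compare.
#' @return data.frame: `variable`, group medians, `statistic` (rank-sum W),
#'   `p`, `q`.
#' @export
compare_cohorts <- function(features, variables = NULL,
                            groups = c("NR", "CR")) {
  if (is.null(variables))
    variables <- names(features)[vapply(features, is.numeric, logical(1))]
  g1 <- features$cohort == groups[1]
  g2 <- features$cohort == groups[2]
  if (!any(g1) || !any(g2))
    imc_stop("both cohorts must be non-empty", "imc_config_error")
  res <- lapply(variables, function(v) {
    x <- features[[v]][g1]; y <- features[[v]][g2]
    ok <- is.finite(x); x <- x[ok]
    ok <- is.finite(y); y <- y[ok]
    if (!length(x) || !length(y))
      return(data.frame(variable = v, median_1 = NA, median_2 = NA,
                        statistic = NA, p = NA))
    if (all(c(x, y) == c(x, y)[1])) {      # all identical: no evidence
      w <- length(x) * length(y) / 2
      return(data.frame(variable = v, median_1 = stats::median(x),
                        median_2 = stats::median(y), statistic = w, p = 1))
    }
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    data.frame(variable = v, median_1 = stats::median(x),
               median_2 = stats::median(y),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("median_", groups)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Cohort cell-count composition summary
#'
#' Aggregates per-cohort total and immune cell counts into the headline
#' composition statistics: the pooled totals, each cohort's share of the
#' pooled immune cells, and each cohort's within-cohort immune fraction
#' (immune cells divided by that cohort's total cells). The two percentages
#' answer different questions and are reported side by side.
#'
#' @param total_cells named vector of total segmented cells per cohort.
#' @param immune_cells named vector of immune cells per cohort (same names).
#' @return list: `total`, `total_immune`, `share_of_immune_pct` (per cohort),
#'   `immune_fraction_of_cohort_pct` (per cohort).
#' @export
composition_summary <- function(total_cells, immune_cells) {
  stopifnot(identical(sort(names(total_cells)), sort(names(immune_cells))))
  immune_cells <- immune_cells[names(total_cells)]
  if (any(immune_cells > total_cells))
    imc_stop("immune counts exceed totals", "imc_value_error")
  list(total = sum(total_cells),
       total_immune = sum(immune_cells),
       share_of_immune_pct = 100 * immune_cells / sum(immune_cells),
       immune_fraction_of_cohort_pct = 100 * immune_cells / total_cells)
}
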