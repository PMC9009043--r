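#' PCA on per-ROI features
#'
#' Columns are centered and (by default) scaled to unit variance, then
#' eigen-decomposed; scaling is the default because IMC markers differ widely
#' in raw signal intensity. Loadings carry a deterministic sign convention
#' (the largest-magnitude loading of each component is positive).
#' Contribution of variable j to component k is
#' `100 * loading[j,k]^2 / sum_i loading[i,k]^2`.
#'
#' @param x ROIs x variables numeric matrix or data.frame (no missing
#'   values).
#' @param scale scale columns to unit variance (default TRUE).
#' @return a `pca_model`: list with `loadings`, `scores`,
#'   `explained_var_pct`, `contrib_pct`, `center`, `scale`.
#' @export
pca_fit <- function(x, scale = TRUE) {
  rid <- if (is.data.frame(x) && "roi_id" %in% names(x)) x$roi_id
  if (is.data.frame(x))
    x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    imc_stop("PCA needs >= 2 ROIs and >= 2 variables", "imc_config_error")
  if (any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)[1]
    imc_stop(sprintf("missing values in ROI %s",
                     if (!is.null(rid)) rid[bad] else bad), "imc_value_error")
  }
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      imc_stop(sprintf("zero-variance column with scale=TRUE: %s",
                       paste(colnames(x)[sds == 0], collapse = ", ")),
               "imc_value_error")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  load <- fit$rotation
  scores <- fit$x
  for (k in seq_len(ncol(load))) {            # sign convention
    if (load[which.max(abs(load[, k])), k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  if (!is.null(rid)) rownames(scores) <- rid
  ev <- fit$sdev^2
  structure(list(
    loadings = load, scores = scores,
    explained_var_pct = 100 * ev / sum(ev),
    contrib_pct = 100 * sweep(load^2, 2L, colSums(load^2), "/"),
    center = fit$center, scale = if (scale) fit$scale else NULL),
    class = "pca_model")
}

#' Wilcoxon rank-sum test on PC1 scores by cohort
#'
#' @param pca a `pca_model` (or a numeric vector of PC1 scores).
#' @param cohort cohort label per ROI.
#' @param groups the two cohorts to compare.
#' @return one-row data.frame as [compare_cohorts()].
#' @export
pc1_test <- function(pca, cohort, groups = c("NR", "CR")) {
  s <- if (inherits(pca, "pca_model")) pca$scores[, 1] else pca
  compare_cohorts(data.frame(cohort = cohort, PC1 = as.numeric(s)),
                  variables = "PC1", groups = groups)
}

# internal: 2-parameter (intercept, slope) logistic regression with an
# optional ridge penalty on the slope, by Newton iterations
ridge_logistic <- function(z, y, ridge = 0, max_iter = 200L) {
  beta <- c(0, 0)
  x <- cbind(1, z)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, y - mu)) - c(0, ridge * beta[2])
    w <- mu * (1 - mu)
    h <- crossprod(x * w, x) + diag(c(1e-10, ridge))
    step <- solve(h, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Logistic regression of cohort on PC1
#'
#' Maximum-likelihood fit of `P(CR) = 1 / (1 + exp(-(a + b * PC1)))`. If the
#' cohorts are completely separated along PC1 (divergent slope -- common with
#' 8-vs-24 designs and strong effects, where the unpenalized MLE does not
#' exist), the model is refit with a ridge penalty of 1.0 on the slope and
#' flagged. Reports per-ROI predicted probabilities, the count of ROIs whose
#' correct-class probability is >= 0.75, and the outliers (correct-class
#' probability < 0.5).
#'
#' @param pca a `pca_model` or numeric PC1 scores.
#' @param cohort cohort labels.
#' @param positive the modeled class (default `"CR"`).
#' @param ridge ridge penalty (default 0 = plain MLE, with the separation
#'   fallback).
#' @return an `lr1_model`: list with `intercept`, `slope`, `ridge`,
#'   `separation` flag, `prob` (per-ROI P(positive)), `correct_prob`,
#'   `n_correct_ge_075`, `n_outliers`, `accuracy`.
#' @export
logistic_pc1 <- function(pca, cohort, positive = "CR", ridge = 0) {
  z <- if (inherits(pca, "pca_model")) pca$scores[, 1] else as.numeric(pca)
  y <- as.integer(cohort == positive)
  if (all(y == 1L) || all(y == 0L))
    imc_stop("both classes must be present", "imc_config_error")
  separation <- FALSE
  if (ridge > 0) {
    beta <- ridge_logistic(z, y, ridge)
  } else {
    beta <- tryCatch(
      stats::coef(suppressWarnings(
        stats::glm(y ~ z, family = stats::binomial()))),
      error = function(e) c(NA_real_, NA_real_))
    separated <- max(z[y == 0L]) < min(z[y == 1L]) ||
      max(z[y == 1L]) < min(z[y == 0L])
    if (separated || any(!is.finite(beta)) || abs(beta[2]) > 50) {
      separation <- TRUE
      ridge <- 1.0
      beta <- ridge_logistic(z, y, ridge)
    }
  }
  prob <- 1 / (1 + exp(-(beta[1] + beta[2] * z)))
  correct <- ifelse(y == 1L, prob, 1 - prob)
  structure(list(
    intercept = unname(beta[1]), slope = unname(beta[2]), ridge = ridge,
    separation = separation, prob = prob, cohort = cohort,
    correct_prob = correct,
    n_correct_ge_075 = sum(correct >= 0.75),
    n_outliers = sum(correct < 0.5),
    accuracy = mean((prob >= 0.5) == (y == 1L))),
    class = "lr1_model")
}

#' Marker correlation network
#'
#' Pairwise correlations across the feature columns (Spearman by default; the
#' coefficient is configurable because rank correlation is robust to the
#' heavy-tailed raw IMC intensities); edges where `|r| >= threshold`.
#' Constant columns yield missing correlations and no edges.
#'
#' @param x ROIs x variables matrix or data.frame (>= 3 ROIs).
#' @param method correlation coefficient (`"spearman"` or `"pearson"`).
#' @param threshold absolute-correlation edge threshold.
#' @return data.frame edge list: `var_a`, `var_b`, `r`.
#' @export
correlation_network <- function(x, method = c("spearman", "pearson"),
                                threshold = 0.8) {
  method <- match.arg(method)
  if (is.data.frame(x))
    x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) < 3)
    imc_stop("correlation network needs >= 3 ROIs", "imc_config_error")
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x, method = method))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  v <- colnames(x)
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) >= threshold, arr.ind = TRUE)
  out <- data.frame(var_a = v[idx[, 1]], var_b = v[idx[, 2]],
                    r = r[idx])
  out[order(out$var_a, out$var_b), , drop = FALSE]
}
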