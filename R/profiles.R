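#' Phenotype expression profiles
#'
#' A phenotype profile describes one simulated cell population: its mean
#' marker intensities (ion-count units), the per-marker coefficient of
#' variation of the lognormal cell-to-cell expression draw, whether the
#' phenotype is an immune population, and its mean radius in pixels.
#'
#' @param name phenotype label.
#' @param immune logical.
#' @param marker_means named numeric vector, one entry per panel marker, >= 0.
#' @param marker_cv scalar or per-marker coefficient of variation.
#' @param radius_px mean cell radius in pixels.
#' @param panel the panel the means refer to.
#' @return a `phenotype_profile` list.
#' @export
phenotype_profile <- function(name, immune, marker_means, marker_cv = 0.25,
                              radius_px = 3.5, panel = default_panel()) {
  validate_panel(panel)
  unknown <- setdiff(names(marker_means), panel$marker)
  if (length(unknown))
    imc_stop(sprintf("profile '%s' names markers not in the panel: %s",
                     name, paste(unknown, collapse = ", ")),
             "imc_config_error")
  means <- stats::setNames(numeric(nrow(panel)), panel$marker)
  means[names(marker_means)] <- marker_means
  if (any(means < 0))
    imc_stop("marker means must be >= 0", "imc_config_error")
  if (means[nuclear_marker(panel)] <= 0)
    imc_stop(sprintf("profile '%s' must have positive nuclear-channel mean",
                     name), "imc_config_error")
  cv <- stats::setNames(rep_len(marker_cv, nrow(panel)), panel$marker)
  structure(list(name = name, immune = isTRUE(immune), marker_means = means,
                 marker_cv = cv, radius_px = radius_px),
            class = "phenotype_profile")
}

#' Default phenotype profiles for the liver-allograft panel
#'
#' Returns the 11 immune phenotypes observed in chronic liver-allograft
#' rejection (B-cell, HLADR+, Naive T-cell, Other Leukocyte, Neutrophil,
#' CTL-1, CTL-2, Macrophage-1, Macrophage-2, Other T-cell-1, Other T-cell-2)
#' plus one non-immune hepatocyte profile. Marker patterns follow the field's
#' immunophenotyping conventions: CTLs are CD45+/CD3+/CD8+, macrophages are
#' CD68+ with no CD3 expression, B-cells CD20+, neutrophils CD66a+, naive
#' T-cells CD45RA+, and paired populations of the same identity (e.g. CTL-1
#' vs CTL-2) differ by signal intensity, mirroring Phenograph splitting
#' clusters on intensity rather than marker identity. All cells carry an
#' iridium nucleus. Hepatocytes express none of the 8 immune markers and are
#' larger (radius 5 px vs ~3.5 px at 1 um/px).
#'
#' @param panel a panel containing the 10 default channels.
#' @return named list of 12 `phenotype_profile` objects.
#' @export
default_profiles <- function(panel = default_panel()) {
  validate_panel(panel)
  need <- default_panel()$marker
  missing <- setdiff(need, panel$marker)
  if (length(missing))
    imc_stop(sprintf("panel is missing default channels: %s",
                     paste(missing, collapse = ", ")), "imc_config_error")
  nuc <- c(Iridium = 25)
  p <- function(name, immune, means, radius = 3.5)
    phenotype_profile(name, immune, c(means, nuc), marker_cv = 0.25,
                      radius_px = radius, panel = panel)
  profs <- list(
    p("B-cell",          TRUE, c(CD20 = 30)),
    p("HLADR+",          TRUE, c(HLADR = 25)),
    p("Naive T-cell",    TRUE, c(CD45RA = 25, CD45 = 4)),
    p("Other Leukocyte", TRUE, c(CD45 = 20)),
    p("Neutrophil",      TRUE, c(CD66a = 25)),
    p("CTL-1",           TRUE, c(CD45 = 15, CD3 = 20, CD8 = 18)),
    p("CTL-2",           TRUE, c(CD45 = 8, CD3 = 35, CD8 = 40)),
    p("Macrophage-1",    TRUE, c(CD68 = 20, HLADR = 8), radius = 4),
    p("Macrophage-2",    TRUE, c(CD68 = 45), radius = 4),
    p("Other T-cell-1",  TRUE, c(CD45 = 18, CD3 = 25)),
    p("Other T-cell-2",  TRUE, c(CD45 = 5, CD3 = 30)),
    p("not immune cell", FALSE, NULL, radius = 5)
  )
  stats::setNames(profs, vapply(profs, `[[`, character(1), "name"))
}
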