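#' Marker panels
#'
#' A marker panel maps the channels of an IMC acquisition to marker names and
#' roles. Panels are plain data frames with columns `channel_index` (0-based,
#' contiguous), `marker` (unique names), `role` (one of `"immune"`,
#' `"structural"`, `"nuclear"`) and `metal_tag` (informational only).
#' Exactly one channel must be nuclear.
#'
#' @name marker_panel
NULL

#' Construct and validate a marker panel
#'
#' @param marker character vector of unique marker names.
#' @param role character vector of roles (`immune`, `structural`, `nuclear`).
#' @param metal_tag optional character vector of isotope tags.
#' @return a validated `marker_panel` data frame.
#' @export
marker_panel <- function(marker, role, metal_tag = NA_character_) {
  panel <- data.frame(
    channel_index = seq_along(marker) - 1L,
    marker = as.character(marker),
    role = as.character(role),
    metal_tag = rep_len(as.character(metal_tag), length(marker)),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @rdname marker_panel
#' @param panel a panel data frame to validate.
#' @export
validate_panel <- function(panel) {
  req <- c("channel_index", "marker", "role")
  if (!all(req %in% names(panel)))
    imc_stop(sprintf("panel is missing columns: %s",
                     paste(setdiff(req, names(panel)), collapse = ", ")),
             "imc_format_error")
  if (anyDuplicated(panel$marker))
    imc_stop("panel marker names must be unique", "imc_format_error")
  if (!identical(as.integer(panel$channel_index),
                 seq_len(nrow(panel)) - 1L))
    imc_stop("panel channel indices must be contiguous from 0",
             "imc_format_error")
  bad <- setdiff(unique(panel$role), c("immune", "structural", "nuclear"))
  if (length(bad))
    imc_stop(sprintf("unknown panel roles: %s", paste(bad, collapse = ", ")),
             "imc_format_error")
  if (sum(panel$role == "nuclear") != 1L)
    imc_stop("panel must contain exactly one nuclear channel",
             "imc_format_error")
  invisible(panel)
}

#' The default 10-channel liver-transplant panel
#'
#' Eight immune markers (CD20 B-cells, CD68 macrophages, CD66a neutrophils,
#' CD45 pan-leukocyte, CD45RA naive T-cells, CD3 T-cell receptor, CD8
#' cytotoxic T-cells, HLADR), collagen-1 as the structural channel, and an
#' iridium nuclear intercalator.
#'
#' @return a `marker_panel` with 10 channels.
#' @export
default_panel <- function() {
  marker_panel(
    marker = c("CD20", "CD68", "CD66a", "CD45", "CD45RA", "CD3", "CD8",
               "HLADR", "Collagen1", "Iridium"),
    role = c(rep("immune", 8L), "structural", "nuclear"),
    metal_tag = c("Dy161", "Tb159", "Sm152", "Sm147", "Eu153", "Er170",
                  "Dy162", "Yb174", "Tm169", "Ir191")
  )
}

#' @rdname marker_panel
#' @export
immune_markers <- function(panel) panel$marker[panel$role == "immune"]

#' @rdname marker_panel
#' @export
nuclear_marker <- function(panel) panel$marker[panel$role == "nuclear"]

#' Read / write a panel CSV
#'
#' @param path file path.
#' @return `read_panel` returns a validated `marker_panel`.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @rdname read_panel
#' @param panel panel to write.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
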