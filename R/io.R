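#' ROI image container
#'
#' An ROI (region of interest) image is one ablated tissue rectangle: a
#' channels x rows x cols intensity stack plus panel metadata. Intensities are
#' raw ion counts; the pipeline never log- or arcsinh-transforms them.
#'
#' @param stack numeric array, `channels x rows x cols`, finite and >= 0.
#' @param panel a [marker_panel()] whose length matches the channel count.
#' @param roi_id text identifier.
#' @param cohort `"NR"`, `"CR"` or `"unknown"`.
#' @param pixel_size_um physical pixel size (default 1 micron, the ablation
#'   spot size of the acquisition).
#' @return a `roi_image` list.
#' @export
roi_image <- function(stack, panel, roi_id = "roi", cohort = "unknown",
                      pixel_size_um = 1.0) {
  validate_panel(panel)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (dim(stack)[1] != nrow(panel))
    imc_stop(sprintf("stack has %d channels but panel has %d",
                     dim(stack)[1], nrow(panel)), "imc_format_error")
  if (!all(is.finite(stack)) || any(stack < 0))
    imc_stop("stack intensities must be finite and >= 0", "imc_format_error")
  if (!cohort %in% c("NR", "CR", "unknown"))
    imc_stop("cohort must be NR, CR or unknown", "imc_format_error")
  structure(list(roi_id = as.character(roi_id), cohort = cohort,
                 pixel_size_um = pixel_size_um, stack = stack,
                 panel = panel),
            class = "roi_image")
}

#' Extract one channel of an ROI as a rows x cols matrix
#'
#' @param roi a `roi_image`.
#' @param marker marker name.
#' @return numeric matrix.
#' @export
roi_channel <- function(roi, marker) {
  i <- match(marker, roi$panel$marker)
  if (is.na(i))
    imc_stop(sprintf("marker '%s' not in panel", marker), "imc_format_error")
  matrix(roi$stack[i, , ], dim(roi$stack)[2], dim(roi$stack)[3])
}

# internal: write a list of rows x cols matrices as a multi-page TIFF.
# Integer data <= 65535 is stored losslessly as 16-bit; anything else is
# stored as 32-bit float scaled by 2^-24 (exact for integers < 2^24).
write_stack_tiff <- function(mats, path) {
  vals <- unlist(lapply(mats, range))
  if (any(vals < 0)) imc_stop("negative values cannot be written",
                              "imc_value_error")
  is_int <- all(vapply(mats, function(m) all(m == floor(m)), logical(1)))
  if (is_int && max(vals) <= 65535) {
    tiff::writeTIFF(lapply(mats, function(m) m / 65535), path,
                    bits.per.sample = 16L, compression = "none")
  } else {
    if (max(vals) >= 2^24)
      imc_stop("values >= 2^24 are not representable in the 32-bit format",
               "imc_value_error")
    tiff::writeTIFF(lapply(mats, function(m) m / 2^24), path,
                    bits.per.sample = 32L, compression = "none")
  }
  invisible(path)
}

# internal: read a multi-page TIFF back to a list of matrices, undoing the
# scaling chosen by write_stack_tiff. `integer_data` forces rounding (masks).
read_stack_tiff <- function(path, integer_data = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate accidental RGB pages
    m <- if (!is.null(bits) && bits == 16L) round(p * 65535) else p * 2^24
    if (integer_data) m <- round(m)
    attributes(m) <- list(dim = dim(p))        # drop TIFF info attributes
    m
  })
}

#' Write / read an ROI image stack as a multi-channel TIFF
#'
#' One TIFF page per channel, in panel order. Integer count data (the usual
#' case for raw IMC) round-trips bit-identically via 16-bit storage; continuous
#' data falls back to 32-bit floats.
#'
#' @param roi a `roi_image`.
#' @param path file path.
#' @return `read_roi` returns a `roi_image`.
#' @export
write_roi <- function(roi, path) {
  nch <- dim(roi$stack)[1]
  mats <- lapply(seq_len(nch), function(i) roi_channel(roi, roi$panel$marker[i]))
  write_stack_tiff(mats, path)
}

#' @rdname write_roi
#' @param panel panel describing the expected channels.
#' @param roi_id,cohort,pixel_size_um metadata for the returned object (TIFF
#'   pages carry no cohort tag, so cohort defaults to `"unknown"`).
#' @export
read_roi <- function(path, panel, roi_id = basename(path),
                     cohort = "unknown", pixel_size_um = 1.0) {
  validate_panel(panel)
  mats <- tryCatch(read_stack_tiff(path),
                   error = function(e) imc_stop(
                     sprintf("'%s' is not a readable TIFF: %s",
                             path, conditionMessage(e)), "imc_format_error"))
  if (length(mats) != nrow(panel))
    imc_stop(sprintf("channel mismatch: expected %d channels (panel), found %d in '%s'",
                     nrow(panel), length(mats), path), "imc_format_error")
  stack <- array(0, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) stack[i, , ] <- mats[[i]]
  roi_image(stack, panel, roi_id = roi_id, cohort = cohort,
            pixel_size_um = pixel_size_um)
}

#' Write / read a label mask TIFF
#'
#' Label masks are 2D integer images, 0 = background, k > 0 = cell k. Labels
#' up to 65535 are stored as 16-bit; larger labels fall back to 32-bit
#' storage (exact below 2^24). Round trips are lossless.
#'
#' @param mask integer matrix of labels.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask < 0)) imc_stop("mask labels must be >= 0", "imc_value_error")
  if (any(mask != floor(mask)))
    imc_stop("mask labels must be integers", "imc_value_error")
  write_stack_tiff(list(mask), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_stack_tiff(path, integer_data = TRUE)[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read the per-cell measurement table
#'
#' CSV with header `roi_id, cell_id, centroid_row, centroid_col, area_px`,
#' then one column per marker (per-cell mean intensity). Floats are written
#' with full precision (15 significant digits), so round trips agree to
#' better than 1e-9.
#'
#' @param cells a cell-table data frame.
#' @param path file path.
#' @param panel optional panel; when given, the marker columns are checked.
#' @export
write_cell_table <- function(cells, path, panel = NULL) {
  validate_cell_table(cells, panel)
  data.table::fwrite(cells, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, panel = NULL) {
  cells <- as.data.frame(data.table::fread(path))
  validate_cell_table(cells, panel)
  cells
}

#' @rdname write_cell_table
#' @export
validate_cell_table <- function(cells, panel = NULL) {
  req <- c("roi_id", "cell_id", "centroid_row", "centroid_col", "area_px")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    imc_stop(sprintf("cell table is missing columns: %s",
                     paste(miss, collapse = ", ")), "imc_schema_error")
  if (!is.null(panel)) {
    miss <- setdiff(panel$marker, names(cells))
    if (length(miss))
      imc_stop(sprintf("cell table is missing marker columns: %s",
                       paste(miss, collapse = ", ")), "imc_schema_error")
  }
  if (anyDuplicated(cells[, c("roi_id", "cell_id")]))
    imc_stop("duplicate (roi_id, cell_id) in cell table", "imc_integrity_error")
  invisible(cells)
}
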