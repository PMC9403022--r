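# File formats: 8-bit PNG images and label masks, expression TSV,
# GMT gene sets, and JSON sidecars for ROI boxes and patch grids.

#' Read and write RGB images and label masks as PNG
#'
#' Images are 8-bit RGB; masks are single-channel 8-bit PNG storing the
#' label codes 0 (background), 1 (epithelium), 2 (stroma) directly as
#' pixel values.
#'
#' @param img Numeric H x W x 3 array (0-255).
#' @param mask Integer label matrix.
#' @param path File path.
#' @return Readers return the array/matrix; writers return `path`
#'   invisibly.
#' @export
write_image_png <- function(img, path) {
  check_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  round(x[, , 1:3, drop = FALSE] * 255)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  check_mask(m)
  m
}

#' Read and write expression matrices as TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path File path.
#' @return `read_expression_tsv()` returns the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write gene-set collections in GMT format
#'
#' One term per line: term ID, description, then member genes, all
#' tab-separated.
#'
#' @param sets A `"gene_sets"` named list (see [generate_annotation()]).
#' @param path File path.
#' @return `read_gmt()` returns a `"gene_sets"` object.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  structure(sets, descriptions = desc, class = "gene_sets")
}

#' Write ROI and patch-grid sidecars as JSON
#'
#' @param roi A [roi_from_mask()] box.
#' @param grid A [tile_roi()] grid.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
write_grid_json <- function(grid, path) {
  obj <- list(patch_w = grid$patch_w, patch_h = grid$patch_h,
              bg_threshold = grid$bg_threshold, roi = unclass(grid$roi),
              tiles = grid$tiles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
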