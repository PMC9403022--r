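# Whole-slide processing: downsample, CIELAB chroma clustering for
# foreground detection, largest-connected-component ROI extraction,
# fixed-size tiling with a background-discard rule, and stitching of
# patch-level predictions into a global tissue mask.
#
# Conventions: coordinates are row-major, 0-based and half-open everywhere;
# patch size is width x height (a 1128 x 720 patch is 1128 wide, 720 tall).

#' Downsample a slide by block averaging
#'
#' Each output pixel is the mean of its `factor` x `factor` source block
#' (partial blocks at the bottom/right edges average over their actual
#' pixels). Output dimensions are `ceiling(dim / factor)`.
#'
#' @param slide Numeric H x W x 3 RGB array (0-255).
#' @param factor Positive integer downsampling factor (default 16).
#' @return Downsampled RGB array with attribute `"factor"`.
#' @export
downsample_slide <- function(slide, factor = 16L) {
  check_rgb(slide, "slide")
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  h <- dim(slide)[1]
  w <- dim(slide)[2]
  gi <- ceiling(seq_len(h) / factor)
  gj <- ceiling(seq_len(w) / factor)
  cnt <- outer(tabulate(gi), tabulate(gj))
  out <- array(0, c(max(gi), max(gj), 3))
  for (ch in 1:3) {
    s <- rowsum(slide[, , ch], gi, reorder = TRUE)
    s <- t(rowsum(t(s), gj, reorder = TRUE))
    out[, , ch] <- s / cnt
  }
  attr(out, "factor") <- factor
  out
}

#' Convert an RGB slide to CIELAB chroma (a*, b*)
#'
#' Converts under sRGB/D65 (standard IEC 61966-2-1 linearization and
#' RGB-to-XYZ matrix) and discards the lightness channel L*, keeping only
#' the two colour-opponent chroma channels: stain colour, not brightness,
#' is what separates tissue from the unstained background.
#'
#' @param slide Numeric H x W x 3 RGB array (0-255).
#' @return Numeric H x W x 2 array with slices `a` and `b`.
#' @export
rgb_to_ab <- function(slide) {
  check_rgb(slide, "slide")
  h <- dim(slide)[1]
  w <- dim(slide)[2]
  v <- cbind(as.vector(slide[, , 1]), as.vector(slide[, , 2]),
             as.vector(slide[, , 3])) / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.95047, 1, 1.08883)            # D65
  t3 <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  fxyz <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  ab <- array(0, c(h, w, 2), dimnames = list(NULL, NULL, c("a", "b")))
  ab[, , 1] <- 500 * (fxyz[, 1] - fxyz[, 2])
  ab[, , 2] <- 200 * (fxyz[, 2] - fxyz[, 3])
  ab
}

#' Detect foreground tissue by K-means on chroma
#'
#' Partitions the (a*, b*) pixels into two clusters (K-means, 10 random
#' restarts, seeded) and labels the cluster containing the upper-left pixel
#' as background (0), the other as foreground (1) — slide corners are
#' usually unstained. If the image is constant the mask degenerates to
#' all-background and a warning is signalled. Note the documented failure
#' mode: tissue touching the upper-left corner pixel is labelled background
#' by this rule.
#'
#' @param ab H x W x 2 chroma array from [rgb_to_ab()].
#' @param seed Integer seed for the K-means restarts.
#' @return Integer H x W matrix, 0 = background, 1 = foreground.
#' @export
cluster_foreground <- function(ab, seed = 1L) {
  if (!is.array(ab) || length(dim(ab)) != 3 || dim(ab)[3] != 2) {
    stop("ab must be an H x W x 2 array")
  }
  h <- dim(ab)[1]
  w <- dim(ab)[2]
  x <- cbind(as.vector(ab[, , 1]), as.vector(ab[, , 2]))
  if (nrow(unique(x)) < 2) {
    warning("degenerate chroma image: all pixels identical; ",
            "returning an all-background mask")
    return(matrix(0L, h, w))
  }
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = 10))
  ul <- km$cluster[1]  # linear index 1 = pixel (row 1, col 1)
  matrix(as.integer(km$cluster != ul), h, w)
}

#' Extract the full-resolution ROI from a foreground mask
#'
#' Finds the largest 8-connected foreground component in the low-resolution
#' mask (ties broken by the component whose first pixel comes earliest in
#' row-major scan order), takes its bounding box, and maps it to
#' full-resolution coordinates by multiplying offsets by `factor` and
#' clamping to the slide bounds.
#'
#' @param mask Binary low-resolution matrix from [cluster_foreground()].
#' @param factor Downsampling factor relating mask to slide.
#' @param slide_dims Full-resolution `c(height, width)`.
#' @return An object of class `"roi_box"`: list with 0-based half-open
#'   `row_start`, `row_end`, `col_start`, `col_end`.
#' @export
roi_from_mask <- function(mask, factor, slide_dims) {
  check_mask(mask, codes = 0:1, what = "foreground mask")
  stopifnot(length(slide_dims) == 2, factor >= 1)
  if (sum(mask) == 0) stop("foreground mask is empty: no tissue detected")
  lab <- .label_components(matrix(as.integer(mask), nrow(mask)))
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # row-major index of each candidate's first pixel
    first_rm <- vapply(best, function(l) {
      idx <- which(lab == l)
      r <- ((idx - 1) %% nrow(lab)) + 1
      cc <- ((idx - 1) %/% nrow(lab)) + 1
      min((r - 1) * ncol(lab) + (cc - 1))
    }, numeric(1))
    best <- best[which.min(first_rm)]
  }
  idx <- which(lab == best)
  r <- ((idx - 1) %% nrow(lab)) + 1
  cc <- ((idx - 1) %/% nrow(lab)) + 1
  structure(list(
    row_start = as.integer((min(r) - 1) * factor),
    row_end = as.integer(min(max(r) * factor, slide_dims[1])),
    col_start = as.integer((min(cc) - 1) * factor),
    col_end = as.integer(min(max(cc) * factor, slide_dims[2]))
  ), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI rows [%d, %d), cols [%d, %d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

roi_dims <- function(roi) {
  c(roi$row_end - roi$row_start, roi$col_end - roi$col_start)
}

#' Tile an ROI into fixed-size patches with a background-discard rule
#'
#' Lays a non-overlapping grid of `patch_w` x `patch_h` tiles anchored at
#' the ROI top-left. Edge tiles are conceptually padded with background to
#' full patch size; each tile's background fraction is computed over the
#' full `patch_w * patch_h` pixels. A tile is retained iff its background
#' fraction is `<= bg_threshold`: strictly more than 80% background is
#' discarded, exactly 80% is retained.
#'
#' @param roi A [roi_from_mask()] box.
#' @param foreground_full Full-resolution binary matrix (slide dimensions);
#'   1 = foreground.
#' @param patch_w,patch_h Patch width and height in pixels.
#' @param bg_threshold Maximum background fraction retained (default 0.8).
#' @return An object of class `"patch_grid"`: `patch_w`, `patch_h`, `roi`,
#'   and a data frame `tiles` with 0-based tile offsets `row`, `col`
#'   (relative to the ROI), `bg_fraction` and `retained`.
#' @export
tile_roi <- function(roi, foreground_full, patch_w = 1128L, patch_h = 720L,
                     bg_threshold = 0.8) {
  stopifnot(inherits(roi, "roi_box"), patch_w >= 1, patch_h >= 1)
  check_mask(foreground_full, codes = 0:1, what = "foreground raster")
  dims <- roi_dims(roi)
  stopifnot(dims[1] >= 1, dims[2] >= 1,
            roi$row_end <= nrow(foreground_full),
            roi$col_end <= ncol(foreground_full))
  row_off <- seq(0L, dims[1] - 1L, by = patch_h)
  col_off <- seq(0L, dims[2] - 1L, by = patch_w)
  tiles <- expand.grid(col = as.integer(col_off), row = as.integer(row_off))
  tiles <- tiles[, c("row", "col")]
  area <- as.numeric(patch_w) * patch_h
  tiles$bg_fraction <- vapply(seq_len(nrow(tiles)), function(i) {
    r0 <- roi$row_start + tiles$row[i]
    c0 <- roi$col_start + tiles$col[i]
    r1 <- min(r0 + patch_h, roi$row_end)
    c1 <- min(c0 + patch_w, roi$col_end)
    fg <- sum(foreground_full[(r0 + 1):r1, (c0 + 1):c1])
    (area - fg) / area
  }, numeric(1))
  tiles$retained <- tiles$bg_fraction <= bg_threshold
  structure(list(patch_w = as.integer(patch_w),
                 patch_h = as.integer(patch_h),
                 bg_threshold = bg_threshold, roi = roi, tiles = tiles),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch grid %d x %d px: %d tiles, %d retained\n",
              x$patch_w, x$patch_h, nrow(x$tiles), sum(x$tiles$retained)))
  invisible(x)
}

#' Stitch per-patch predictions into a global tissue mask
#'
#' Places each retained tile's predicted mask at its tile footprint inside
#' the ROI (cropping where the tile was edge-padded); discarded tiles stay
#' background.
#'
#' @param grid A [tile_roi()] grid.
#' @param patch_masks List with one `patch_h` x `patch_w` label mask per
#'   retained tile, in the grid's tile order.
#' @return Integer matrix of ROI dimensions with labels 0/1/2.
#' @export
stitch_predictions <- function(grid, patch_masks) {
  stopifnot(inherits(grid, "patch_grid"))
  keep <- which(grid$tiles$retained)
  if (length(patch_masks) != length(keep)) {
    stop("need exactly one patch mask per retained tile (",
         length(keep), "), got ", length(patch_masks))
  }
  dims <- roi_dims(grid$roi)
  out <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(keep)) {
    m <- patch_masks[[i]]
    if (!is.matrix(m) || nrow(m) != grid$patch_h || ncol(m) != grid$patch_w) {
      stop("patch mask ", i, " is not ", grid$patch_h, " x ", grid$patch_w)
    }
    r0 <- grid$tiles$row[keep[i]]
    c0 <- grid$tiles$col[keep[i]]
    he <- min(grid$patch_h, dims[1] - r0)
    we <- min(grid$patch_w, dims[2] - c0)
    out[(r0 + 1):(r0 + he), (c0 + 1):(c0 + we)] <-
      as.integer(m[seq_len(he), seq_len(we)])
  }
  out
}

# Extract a full-size patch from the slide at a tile footprint, padding
# out-of-ROI area with the background colour.
extract_patch <- function(slide, grid, tile_idx, pad_value = 255) {
  r0 <- grid$roi$row_start + grid$tiles$row[tile_idx]
  c0 <- grid$roi$col_start + grid$tiles$col[tile_idx]
  he <- min(grid$patch_h, grid$roi$row_end - r0)
  we <- min(grid$patch_w, grid$roi$col_end - c0)
  patch <- array(pad_value, c(grid$patch_h, grid$patch_w, 3))
  patch[seq_len(he), seq_len(we), ] <- slide[(r0 + 1):(r0 + he),
                                             (c0 + 1):(c0 + we), , drop = FALSE]
  patch
}

#' Run the full slide-processing pipeline
#'
#' Composes the whole chain: x`factor` downsample, CIELAB chroma
#' conversion, K-means foreground detection, largest-component ROI,
#' nearest-neighbour upsampling of the foreground mask, tiling with the
#' background-discard rule, per-patch segmentation, and stitching into a
#' global tissue mask. All intermediates are returned for audit.
#'
#' @param slide Numeric H x W x 3 RGB array (0-255).
#' @param model Either a trained [build_model()] network or a function
#'   `function(patch_rgb)` returning a `patch_h` x `patch_w` label mask
#'   (e.g. a ground-truth segmenter).
#' @param patch_w,patch_h Tile dimensions (defaults 1128 x 720).
#' @param bg_threshold Background-discard threshold (default 0.8).
#' @param factor Downsampling factor (default 16).
#' @param seed Seed for the K-means step.
#' @return List with `roi`, `grid`, `mask` (stitched ROI tissue mask),
#'   `foreground` (low-resolution K-means mask) and `factor`.
#' @export
process_slide <- function(slide, model, patch_w = 1128L, patch_h = 720L,
                          bg_threshold = 0.8, factor = 16L, seed = 1L) {
  check_rgb(slide, "slide")
  small <- downsample_slide(slide, factor)
  ab <- rgb_to_ab(small)
  m1 <- cluster_foreground(ab, seed = seed)
  roi <- roi_from_mask(m1, factor, dim(slide)[1:2])
  fg_full <- m1[ceiling(seq_len(dim(slide)[1]) / factor),
                ceiling(seq_len(dim(slide)[2]) / factor), drop = FALSE]
  grid <- tile_roi(roi, fg_full, patch_w, patch_h, bg_threshold)
  predict_fun <- if (is.function(model)) {
    model
  } else if (inherits(model, "segnet_model")) {
    function(patch) predict_patch(model, patch)
  } else {
    stop("model must be a segnet_model or a function(patch) -> mask")
  }
  keep <- which(grid$tiles$retained)
  masks <- lapply(keep, function(i) {
    predict_fun(extract_patch(slide, grid, i))
  })
  mask <- stitch_predictions(grid, masks)
  list(roi = roi, grid = grid, mask = mask, foreground = m1,
       factor = as.integer(factor))
}
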