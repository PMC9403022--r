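# ROI pipeline: downsampling, chroma conversion, foreground clustering,
# ROI extraction, tiling, stitching, and the composed slide processor.

test_that("block-mean downsampling matches a brute-force oracle", {
  # constant image collapses to itself
  const <- array(rep(c(10, 150, 200), each = 32 * 32), c(32, 32, 3))
  d <- downsample_slide(const, 16)
  expect_equal(dim(d), c(2, 2, 3))
  expect_true(all(abs(d[, , 1] - 10) < 1e-12))
  # factor 1 is the identity
  img <- array(runif(12 * 10 * 3, 0, 255), c(12, 10, 3))
  expect_equal(as.vector(downsample_slide(img, 1)), as.vector(img))
  # 33 x 33, factor 16: 3 x 3 output, partial edge blocks averaged
  img <- array(runif(33 * 33 * 3, 0, 255), c(33, 33, 3))
  d <- downsample_slide(img, 16)
  expect_equal(dim(d)[1:2], c(3, 3))
  oracle <- function(ch, bi, bj) {
    rows <- ((bi - 1) * 16 + 1):min(bi * 16, 33)
    cols <- ((bj - 1) * 16 + 1):min(bj * 16, 33)
    mean(img[rows, cols, ch])
  }
  for (bi in 1:3) for (bj in 1:3) {
    expect_equal(d[bi, bj, 2], oracle(2, bi, bj))
  }
  expect_error(downsample_slide(img, 0), "positive integer")
})

test_that("chroma conversion agrees with independent sRGB/D65 colorimetry", {
  # neutral colors carry zero chroma
  white <- array(255, c(1, 1, 3))
  expect_lt(max(abs(rgb_to_ab(white))), 1e-3)
  gray <- array(87, c(2, 2, 3))
  expect_lt(max(abs(rgb_to_ab(gray))), 1e-3)
  # hand-written sRGB -> XYZ -> Lab reference, independent of convertColor
  ref_lab <- function(rgb) {
    v <- rgb / 255
    lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
    M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                  0.2126729, 0.7151522, 0.0721750,
                  0.0193339, 0.1191920, 0.9503041), 3, byrow = TRUE)
    xyz <- as.vector(M %*% lin)
    wp <- c(0.95047, 1, 1.08883)  # D65
    f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                            t / (3 * (6 / 29)^2) + 4 / 29)
    fx <- f(xyz / wp)
    c(a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
  }
  set.seed(21)
  for (i in 1:10) {
    rgb <- runif(3, 0, 255)
    got <- rgb_to_ab(array(rgb, c(1, 1, 3)))
    expect_equal(as.vector(got), unname(ref_lab(rgb)), tolerance = 1e-3)
    # library cross-check; convertColor re-derives its sRGB matrix from the
    # chromaticity primaries, which shifts chroma by a few tenths of a unit
    cc <- grDevices::convertColor(matrix(rgb / 255, 1), "sRGB", "Lab")
    expect_lt(max(abs(as.vector(got) - as.vector(cc[2:3]))), 0.6)
  }
})

test_that("K-means foreground follows the upper-left background rule", {
  # left half near-white, right half pink: foreground = pink half
  img <- array(0, c(10, 20, 3))
  img[, 1:10, ] <- rep(c(250, 248, 249), each = 100)
  img[, 11:20, ] <- rep(c(235, 170, 200), each = 100)
  mask <- cluster_foreground(rgb_to_ab(img), seed = 1)
  expect_true(all(mask[, 1:10] == 0))
  expect_true(all(mask[, 11:20] == 1))
  # constant image degenerates with a warning
  expect_warning(m0 <- cluster_foreground(rgb_to_ab(array(128, c(4, 4, 3)))),
                 "degenerate")
  expect_true(all(m0 == 0))
  # documented failure mode: tissue covering the upper-left corner is
  # labelled background by the rule
  swapped <- img[, 20:1, , drop = FALSE]
  m <- cluster_foreground(rgb_to_ab(swapped), seed = 1)
  expect_true(all(m[, 1:10] == 0))  # the pink half, now upper-left
  expect_true(all(m[, 11:20] == 1))
})

test_that("moving the other cluster under the corner pixel flips the mask", {
  # the clustering is position-independent, so cyclically shifting the
  # image until a foreground pixel sits at the upper-left corner must
  # complement the (shifted) mask bitwise
  set.seed(5)
  img <- array(0, c(8, 8, 3))
  purple <- c(150, 90, 170)
  white <- c(250, 249, 251)
  pick <- matrix(runif(64) < 0.4, 8, 8)
  pick[1, 1] <- FALSE
  pick[3, 4] <- TRUE
  for (ch in 1:3) {
    img[, , ch] <- ifelse(pick, purple[ch], white[ch])
  }
  m1 <- cluster_foreground(rgb_to_ab(img), seed = 3)
  expect_identical(m1 == 1L, pick)
  rs <- c(3:8, 1:2)   # cyclic shift putting pixel (3, 4) at the corner
  cs <- c(4:8, 1:3)
  m2 <- cluster_foreground(rgb_to_ab(img[rs, cs, , drop = FALSE]), seed = 3)
  expect_identical(m2, 1L - m1[rs, cs])
})

test_that("ROI extraction finds the largest component and scales x factor", {
  # single 3 x 4 block with top-left at (row 2, col 5), 0-based
  m <- matrix(0L, 10, 10)
  m[3:5, 6:9] <- 1L
  roi <- roi_from_mask(m, 16, c(160, 160))
  expect_equal(roi_as_bbox(roi), c(32, 80, 80, 144))
  # larger of two components wins (sizes 5 and 9)
  m2 <- matrix(0L, 12, 12)
  m2[2, 2:6] <- 1L                 # size 5
  m2[8:10, 8:10] <- 1L             # size 9
  roi2 <- roi_from_mask(m2, 2, c(24, 24))
  expect_equal(roi_as_bbox(roi2), c(14, 20, 14, 20))
  # all-ones mask covers the whole slide
  roi3 <- roi_from_mask(matrix(1L, 4, 6), 16, c(64, 96))
  expect_equal(roi_as_bbox(roi3), c(0, 64, 0, 96))
  expect_error(roi_from_mask(matrix(0L, 4, 4), 16, c(64, 64)), "empty")
})

test_that("component labelling agrees with a brute-force grower", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(as.integer(runif(15 * 15) < 0.35), 15, 15)
    if (sum(m) == 0) next
    # brute force: grow each component by repeated 8-neighbour dilation
    remaining <- which(m == 1)
    comps <- list()
    while (length(remaining) > 0) {
      comp <- remaining[1]
      repeat {
        r <- ((comp - 1) %% 15) + 1
        cc <- ((comp - 1) %/% 15) + 1
        nb <- unique(unlist(lapply(seq_along(comp), function(i) {
          rr <- r[i] + rep(-1:1, 3)
          ccc <- cc[i] + rep(-1:1, each = 3)
          ok <- rr >= 1 & rr <= 15 & ccc >= 1 & ccc <= 15
          rr[ok] + (ccc[ok] - 1) * 15
        })))
        grown <- union(comp, intersect(nb, remaining))
        if (length(grown) == length(comp)) break
        comp <- grown
      }
      comps <- c(comps, list(sort(comp)))
      remaining <- setdiff(remaining, comp)
    }
    sizes <- lengths(comps)
    largest <- comps[[which.max(sizes)]]
    r <- ((largest - 1) %% 15) + 1
    cc <- ((largest - 1) %/% 15) + 1
    roi <- roi_from_mask(m, 1, c(15, 15))
    # only a unique-maximum case is directly comparable
    if (sum(sizes == max(sizes)) == 1) {
      expect_equal(roi_as_bbox(roi),
                   c(min(r) - 1, max(r), min(cc) - 1, max(cc)))
    }
  }
})

test_that("round-trip: a rectangular component returns its own box", {
  m <- matrix(0L, 20, 30)
  m[5:9, 11:18] <- 1L
  roi <- roi_from_mask(m, 4, c(80, 120))
  expect_equal(roi_as_bbox(roi), c(16, 36, 40, 72))
})

test_that("tiling covers the ROI and applies the strict 80% discard rule", {
  # ROI 2256 x 1440 all-foreground: exactly 4 tiles, all retained
  fg <- matrix(1L, 1440, 2256)
  roi <- structure(list(row_start = 0L, row_end = 1440L, col_start = 0L,
                        col_end = 2256L), class = "roi_box")
  grid <- tile_roi(roi, fg, 1128, 720)
  expect_equal(nrow(grid$tiles), 4)
  expect_true(all(grid$tiles$retained))
  # coverage/partition: tile footprints tile the ROI exactly
  cover <- matrix(0L, 1440, 2256)
  for (i in seq_len(nrow(grid$tiles))) {
    r0 <- grid$tiles$row[i]
    c0 <- grid$tiles$col[i]
    rows <- (r0 + 1):min(r0 + grid$patch_h, 1440)
    cols <- (c0 + 1):min(c0 + grid$patch_w, 2256)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover == 1L))
  # boundary: exactly 80% background retained, 85% discarded
  fg2 <- matrix(0L, 20, 30)
  roi2 <- structure(list(row_start = 0L, row_end = 20L, col_start = 0L,
                         col_end = 30L), class = "roi_box")
  fg2[1:4, 1:10] <- 1L   # tile 1 (10 x 20 tiles): 40/200 fg = 80% bg
  fg2[1:3, 11:20] <- 1L  # tile 2: 30/200 fg = 85% bg
  g2 <- tile_roi(roi2, fg2, patch_w = 10, patch_h = 20, bg_threshold = 0.8)
  expect_equal(g2$tiles$bg_fraction, c(0.80, 0.85, 1.00))
  expect_identical(g2$tiles$retained, c(TRUE, FALSE, FALSE))
})

test_that("edge tiles count conceptual padding as background", {
  fg <- matrix(1L, 25, 10)
  roi <- structure(list(row_start = 0L, row_end = 25L, col_start = 0L,
                        col_end = 10L), class = "roi_box")
  g <- tile_roi(roi, fg, patch_w = 10, patch_h = 20, bg_threshold = 0.8)
  # second tile holds 5 x 10 real foreground in a 20 x 10 padded frame
  expect_equal(g$tiles$bg_fraction[2], 0.75)
  expect_true(g$tiles$retained[2])
})

test_that("stitching reassembles per-tile masks in place", {
  fg <- matrix(1L, 8, 8)
  roi <- structure(list(row_start = 0L, row_end = 8L, col_start = 0L,
                        col_end = 8L), class = "roi_box")
  grid <- tile_roi(roi, fg, patch_w = 4, patch_h = 4)
  labs <- list(matrix(1L, 4, 4), matrix(2L, 4, 4),
               matrix(0L, 4, 4), matrix(1L, 4, 4))
  out <- stitch_predictions(grid, labs)
  expect_equal(dim(out), c(8, 8))
  # each quadrant carries its own constant label, in grid tile order
  for (i in seq_len(nrow(grid$tiles))) {
    r0 <- grid$tiles$row[i]
    c0 <- grid$tiles$col[i]
    expect_true(all(out[(r0 + 1):(r0 + 4), (c0 + 1):(c0 + 4)] == labs[[i]]))
  }
  # single retained tile covering the ROI reproduces the patch mask
  g1 <- tile_roi(roi, fg, patch_w = 8, patch_h = 8)
  mm <- matrix(sample(0:2, 64, TRUE), 8, 8)
  expect_equal(stitch_predictions(g1, list(mm)), mm)
  # all tiles discarded -> all-background mask
  g0 <- tile_roi(roi, matrix(0L, 8, 8), patch_w = 4, patch_h = 4)
  expect_true(all(stitch_predictions(g0, list()) == 0L))
  expect_error(stitch_predictions(grid, labs[1:2]), "retained tile")
  expect_error(stitch_predictions(g1, list(matrix(0L, 2, 2))), "not 8 x 8")
})

test_that("the composed pipeline recovers planted geometry and truth masks", {
  s <- small_slide(seed = 17, epi = 0.5)
  res <- process_slide(s$image, function(p) matrix(0L, 96, 128),
                       patch_w = 128, patch_h = 96, factor = 16, seed = 2)
  iou <- bbox_iou(roi_as_bbox(res$roi), mask_bbox(s$mask))
  expect_gt(iou, 0.8)  # small slide; coarse 16x grid costs some IoU
  # with the ground-truth segmenter the stitched mask equals the planted
  # mask restricted to retained tiles
  grid <- res$grid
  masks <- lapply(which(grid$tiles$retained), function(i) {
    r0 <- grid$roi$row_start + grid$tiles$row[i]
    c0 <- grid$roi$col_start + grid$tiles$col[i]
    he <- min(grid$patch_h, grid$roi$row_end - r0)
    we <- min(grid$patch_w, grid$roi$col_end - c0)
    out <- matrix(0L, grid$patch_h, grid$patch_w)
    out[seq_len(he), seq_len(we)] <- s$mask[(r0 + 1):(r0 + he),
                                            (c0 + 1):(c0 + we)]
    out
  })
  stitched <- stitch_predictions(grid, masks)
  for (i in which(grid$tiles$retained)) {
    r0 <- grid$tiles$row[i]
    c0 <- grid$tiles$col[i]
    he <- min(grid$patch_h, nrow(stitched) - r0)
    we <- min(grid$patch_w, ncol(stitched) - c0)
    truth <- s$mask[(grid$roi$row_start + r0 + 1):(grid$roi$row_start + r0 + he),
                    (grid$roi$col_start + c0 + 1):(grid$roi$col_start + c0 + we)]
    expect_identical(stitched[(r0 + 1):(r0 + he), (c0 + 1):(c0 + we)], truth)
  }
  # determinism of the whole pipeline
  res2 <- process_slide(s$image, function(p) matrix(0L, 96, 128),
                        patch_w = 128, patch_h = 96, factor = 16, seed = 2)
  expect_identical(res$mask, res2$mask)
  expect_identical(roi_as_bbox(res$roi), roi_as_bbox(res2$roi))
})
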