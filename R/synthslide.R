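# Synthetic H&E-like slides, labelled patches, expression matrices and
# gene-set annotations with known ground truth. These generators exist so
# that every downstream stage (ROI detection, tiling, segmentation,
# quantification, genomics) can be exercised end to end without external
# data. Texture realism is deliberately limited: the two tissue classes only
# need to be separable by local colour/texture statistics.

#' Specify a synthetic slide
#'
#' Describes a slide of `width_px` x `height_px` pixels with a near-white
#' background and a single tissue region (ellipse or rectangle) strictly
#' inside the slide, split into epithelium and stroma so that the planted
#' epithelial fraction of the tissue area equals `epi_fraction_target`.
#' Epithelium renders as clustered dark-purple nuclei on a lighter purple
#' base (hematoxylin); stroma as pink fibrous texture (eosin).
#'
#' @param width_px,height_px Slide dimensions in pixels.
#' @param tissue_shape `"ellipse"` or `"rectangle"`.
#' @param center Tissue center `c(row, col)`; default slide center.
#' @param axes Semi-axes `c(vertical, horizontal)` in pixels (half-extents
#'   for a rectangle); default derived from `tissue_area_fraction`.
#' @param tissue_area_fraction Fraction of the slide area covered by tissue
#'   when `axes` is `NULL` (default 0.5).
#' @param epi_fraction_target Planted fraction of the tissue area that is
#'   epithelial, in `[0, 1]`.
#' @param nucleus_density_epi,nucleus_density_stro Nuclei per tissue pixel.
#' @param nucleus_radius Nucleus disk radius in pixels.
#' @param fiber_wavelength,fiber_contrast Stromal fiber stripe period (px)
#'   and amplitude (8-bit intensity units).
#' @param fiber_orientation Fiber angle in radians, or `NULL` to draw one
#'   at random per slide.
#' @param background_color Near-white RGB triple (0-255).
#' @param seed Integer seed; all randomness in [generate_slide()] derives
#'   from it.
#' @return An object of class `"slide_spec"`.
#' @export
slide_spec <- function(width_px, height_px,
                       tissue_shape = c("ellipse", "rectangle"),
                       center = NULL, axes = NULL,
                       tissue_area_fraction = 0.5,
                       epi_fraction_target = 0.5,
                       nucleus_density_epi = 0.004,
                       nucleus_density_stro = 0.0008,
                       nucleus_radius = 2,
                       fiber_wavelength = 14, fiber_contrast = 10,
                       fiber_orientation = NULL,
                       background_color = c(246, 244, 247),
                       seed = 1L) {
  tissue_shape <- match.arg(tissue_shape)
  stopifnot(width_px >= 1, height_px >= 1,
            epi_fraction_target >= 0, epi_fraction_target <= 1,
            tissue_area_fraction > 0, tissue_area_fraction < 1,
            length(background_color) == 3)
  if (is.null(center)) center <- c(height_px / 2, width_px / 2)
  if (is.null(axes)) {
    k <- if (tissue_shape == "ellipse") {
      sqrt(tissue_area_fraction / pi)
    } else {
      sqrt(tissue_area_fraction) / 2
    }
    axes <- c(k * height_px, k * width_px)
  }
  if (any(axes <= 0)) stop("degenerate tissue shape: zero area")
  margin <- 0.05 * width_px
  ok <- center[1] - axes[1] >= margin &&
    center[1] + axes[1] <= height_px - margin &&
    center[2] - axes[2] >= margin &&
    center[2] + axes[2] <= width_px - margin
  if (!ok) {
    stop("tissue region must keep a background margin of at least 5% of ",
         "the slide width on all sides")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 tissue_shape = tissue_shape, center = center, axes = axes,
                 epi_fraction_target = epi_fraction_target,
                 nucleus_density_epi = nucleus_density_epi,
                 nucleus_density_stro = nucleus_density_stro,
                 nucleus_radius = nucleus_radius,
                 fiber_wavelength = fiber_wavelength,
                 fiber_contrast = fiber_contrast,
                 fiber_orientation = fiber_orientation,
                 background_color = background_color,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# Smooth Gaussian random field on an h x w grid: coarse white noise,
# Gaussian-blurred, bilinearly upsampled. Drives the epithelial nest shapes.
smooth_field <- function(h, w, coarse = 8) {
  h8 <- max(2L, ceiling(h / coarse))
  w8 <- max(2L, ceiling(w / coarse))
  f <- matrix(rnorm(h8 * w8), h8, w8)
  g1 <- exp(-((-4:4)^2) / (2 * 2^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  f <- .conv2d_fwd(array(f, c(h8, w8, 1)), matrix(as.vector(kern), ncol = 1),
                   0, 9L, 1L, 1L, 4L)[, , 1]
  sy <- h / h8
  sx <- w / w8
  rs <- clamp((seq_len(h) - 0.5) / sy + 0.5, 1, h8)
  cs <- clamp((seq_len(w) - 0.5) / sx + 0.5, 1, w8)
  i0 <- pmin(floor(rs), h8 - 1)
  j0 <- pmin(floor(cs), w8 - 1)
  fr <- rs - i0
  fc <- cs - j0
  f[i0, j0] * outer(1 - fr, 1 - fc) + f[i0 + 1, j0] * outer(fr, 1 - fc) +
    f[i0, j0 + 1] * outer(1 - fr, fc) + f[i0 + 1, j0 + 1] * outer(fr, fc)
}

# Stamp nucleus disks at `centers` (linear indices into an h x w raster)
# onto the channel matrices, restricted to pixels where `region` is TRUE.
stamp_nuclei <- function(chan, centers, region, radius, color, jitter_sd = 8) {
  h <- nrow(region)
  w <- ncol(region)
  if (length(centers) == 0) return(chan)
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[off$di^2 + off$dj^2 <= radius^2, , drop = FALSE]
  r0 <- ((centers - 1L) %% h) + 1L
  c0 <- ((centers - 1L) %/% h) + 1L
  jit <- rnorm(length(centers), 0, jitter_sd)
  for (o in seq_len(nrow(off))) {
    nr <- r0 + off$di[o]
    nc <- c0 + off$dj[o]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    lin <- nr[ok] + (nc[ok] - 1L) * h
    inside <- region[lin]
    lin <- lin[inside]
    jo <- jit[ok][inside]
    for (ch in 1:3) chan[[ch]][lin] <- color[ch] + jo
  }
  chan
}

# Render textures for a labelled region; assumes the RNG is already seeded.
# `tissue` is a logical matrix; returns list(image, mask, achieved).
render_region <- function(tissue, spec) {
  h <- nrow(tissue)
  w <- ncol(tissue)
  n_tis <- sum(tissue)
  target <- spec$epi_fraction_target
  epi <- matrix(FALSE, h, w)
  if (n_tis > 0 && target > 0) {
    if (target >= 1) {
      epi <- tissue
    } else {
      field <- smooth_field(h, w)
      thr <- quantile(field[tissue], 1 - target, names = FALSE)
      epi <- tissue & field > thr
    }
  }
  stro <- tissue & !epi
  mask <- matrix(0L, h, w)
  mask[epi] <- 1L
  mask[stro] <- 2L

  bg <- spec$background_color
  chan <- lapply(1:3, function(ch) matrix(bg[ch] + rnorm(h * w, 0, 2), h, w))
  if (any(stro)) {
    theta <- if (is.null(spec$fiber_orientation)) runif(1, 0, pi) else
      spec$fiber_orientation
    phase <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * (outer(seq_len(h) * cos(theta),
                                seq_len(w) * sin(theta), "+")) /
                  spec$fiber_wavelength + phase)
    base <- c(235, 172, 198)
    mod <- c(1, -1.4, -0.6) * spec$fiber_contrast
    for (ch in 1:3) {
      chan[[ch]][stro] <- base[ch] + mod[ch] * wave[stro] +
        rnorm(sum(stro), 0, 5)
    }
  }
  if (any(epi)) {
    base <- c(188, 148, 208)
    for (ch in 1:3) {
      chan[[ch]][epi] <- base[ch] + rnorm(sum(epi), 0, 5)
    }
    n_nuc <- round(spec$nucleus_density_epi * sum(epi))
    centers <- sample(which(epi), min(n_nuc, sum(epi)))
    chan <- stamp_nuclei(chan, centers, epi, spec$nucleus_radius,
                         c(105, 64, 145))
  }
  if (any(stro)) {
    n_nuc <- round(spec$nucleus_density_stro * sum(stro))
    centers <- sample(which(stro), min(n_nuc, sum(stro)))
    chan <- stamp_nuclei(chan, centers, stro, max(1, spec$nucleus_radius - 1),
                         c(150, 90, 160))
  }
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- clamp(round(chan[[ch]]), 0, 255)
  achieved <- if (n_tis > 0) sum(epi) / n_tis else NA_real_
  list(image = img, mask = mask, achieved = achieved)
}

#' Generate a synthetic H&E-like slide with ground truth
#'
#' Renders the slide described by a [slide_spec()]: near-white jittered
#' background, a single tissue region split into epithelial nests (threshold
#' of a smooth Gaussian random field, so the achieved epithelial fraction
#' matches the planted target to within +/- 0.02) and fibrous stroma.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [slide_spec()].
#' @return A list of class `"synth_slide"` with elements `image` (H x W x 3
#'   array, 0-255), `mask` (integer matrix, 0 = background, 1 = epithelium,
#'   2 = stroma), `achieved_epi_fraction`, and `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height_px
  w <- spec$width_px
  rows <- seq_len(h)
  cols <- seq_len(w)
  if (spec$tissue_shape == "ellipse") {
    tissue <- outer(((rows - spec$center[1]) / spec$axes[1])^2,
                    ((cols - spec$center[2]) / spec$axes[2])^2, "+") <= 1
  } else {
    tissue <- outer(abs(rows - spec$center[1]) <= spec$axes[1],
                    abs(cols - spec$center[2]) <= spec$axes[2], "&")
  }
  if (!any(tissue)) stop("degenerate tissue shape: zero area")
  out <- with_seed(spec$seed, render_region(tissue, spec))
  if (abs(out$achieved - spec$epi_fraction_target) > 0.02) {
    stop("planted epithelial fraction missed its target by more than 0.02")
  }
  structure(list(image = out$image, mask = out$mask,
                 achieved_epi_fraction = out$achieved, spec = spec),
            class = "synth_slide")
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf("synthetic slide %d x %d px, %s tissue, epi fraction %.3f\n",
              x$spec$width_px, x$spec$height_px, x$spec$tissue_shape,
              x$achieved_epi_fraction))
  invisible(x)
}

#' Generate a labelled training patch dataset
#'
#' Produces `n` fully-tissue image/mask pairs whose planted epithelial
#' fractions are drawn uniformly over `epi_fraction_range`. Patches emulate
#' annotated rectangular training regions: tissue fills the whole patch
#' (no background border). Deterministic given `seed`.
#'
#' @param n Number of patches (>= 1).
#' @param patch_w,patch_h Patch dimensions in pixels.
#' @param epi_fraction_range Length-2 range inside `[0, 1]`.
#' @param background_prob Probability that a patch carries a background
#'   band along one edge (width 10-35% of the patch). Default 0: fully
#'   annotated training regions contain tissue only. Set above 0 when the
#'   trained model will also meet slide background at inference time.
#' @param seed Integer seed.
#' @param ... Texture parameters forwarded to [slide_spec()].
#' @return List of `n` lists with elements `image`, `mask`,
#'   `epi_fraction` (achieved over tissue pixels) and `target`.
#' @export
generate_patch_dataset <- function(n, patch_w = 96, patch_h = 96,
                                   epi_fraction_range = c(0.2, 0.8),
                                   background_prob = 0, seed = 1L, ...) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (length(epi_fraction_range) != 2 || any(!is.finite(epi_fraction_range)) ||
      epi_fraction_range[1] > epi_fraction_range[2] ||
      epi_fraction_range[1] < 0 || epi_fraction_range[2] > 1) {
    stop("epi_fraction_range must be an ordered pair inside [0, 1]")
  }
  with_seed(seed, {
    targets <- runif(n, epi_fraction_range[1], epi_fraction_range[2])
    lapply(seq_len(n), function(i) {
      sp <- slide_spec(width_px = patch_w, height_px = patch_h,
                       epi_fraction_target = targets[i], seed = seed, ...)
      tissue <- matrix(TRUE, patch_h, patch_w)
      if (runif(1) < background_prob) {
        side <- sample(4, 1)
        frac <- runif(1, 0.10, 0.35)
        if (side == 1) tissue[seq_len(ceiling(frac * patch_h)), ] <- FALSE
        if (side == 2) tissue[patch_h - seq_len(ceiling(frac * patch_h)) + 1, ] <- FALSE
        if (side == 3) tissue[, seq_len(ceiling(frac * patch_w))] <- FALSE
        if (side == 4) tissue[, patch_w - seq_len(ceiling(frac * patch_w)) + 1] <- FALSE
      }
      out <- render_region(tissue, sp)
      list(image = out$image, mask = out$mask, epi_fraction = out$achieved,
           target = targets[i])
    })
  })
}

#' Specify a synthetic expression matrix
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_planted_epi,n_planted_stro Numbers of genes monotonically tied
#'   to the epithelial and stromal ratios (disjoint sets).
#' @param target_rho Target Spearman correlation in `(0, 1]` between each
#'   planted gene and its tissue ratio.
#' @param noise_sd Scale of expression noise (null genes are i.i.d.
#'   `N(baseline, noise_sd^2)`).
#' @param baseline Additive expression baseline (log2-like units).
#' @param seed Integer seed.
#' @return An object of class `"expression_spec"`.
#' @export
expression_spec <- function(n_genes = 2000, n_samples = 100,
                            n_planted_epi = 10, n_planted_stro = 10,
                            target_rho = 0.8, noise_sd = 1, baseline = 8,
                            seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 3,
            n_planted_epi >= 0, n_planted_stro >= 0,
            n_planted_epi + n_planted_stro <= n_genes,
            target_rho > 0, target_rho <= 1, noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_planted_epi = as.integer(n_planted_epi),
                 n_planted_stro = as.integer(n_planted_stro),
                 target_rho = target_rho, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a synthetic expression matrix with ratio-correlated genes
#'
#' Planted genes follow `g = f(ratio) + noise` with `f` strictly increasing
#' (the normal scores of the ratio), and the noise scale calibrated through
#' the Gaussian-copula rank-correlation identity
#' `rho_s = (6/pi) * asin(rho_p / 2)` so the population Spearman correlation
#' against the ratio equals `spec$target_rho`. Epithelial genes track
#' `ratios`; stromal genes track `1 - ratios`. All remaining genes are
#' i.i.d. Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param ratios Per-sample epithelial tissue ratios (finite numerics).
#' @param spec An [expression_spec()]; `spec$n_samples` must equal
#'   `length(ratios)`.
#' @return List with `expr` (genes x samples matrix with gene/sample IDs),
#'   `planted_epi`, `planted_stro` (character vectors of gene IDs), and
#'   `noise_scale` (the calibrated planted-gene noise SD on the normal-score
#'   scale).
#' @export
generate_expression <- function(ratios, spec) {
  stopifnot(inherits(spec, "expression_spec"))
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  n <- spec$n_samples
  if (length(ratios) != n) stop("length(ratios) must equal spec$n_samples")
  rho_p <- 2 * sin(pi * spec$target_rho / 6)
  sigma <- sqrt(1 / rho_p^2 - 1)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- sprintf("S%03d", seq_len(n))
  with_seed(spec$seed, {
    planted <- sample(genes, spec$n_planted_epi + spec$n_planted_stro)
    p_epi <- planted[seq_len(spec$n_planted_epi)]
    p_stro <- setdiff(planted, p_epi)
    z_epi <- qnorm((rank(ratios) - 0.5) / n)
    z_stro <- qnorm((rank(1 - ratios) - 0.5) / n)
    expr <- matrix(rnorm(spec$n_genes * n, spec$baseline, spec$noise_sd),
                   spec$n_genes, n, dimnames = list(genes, samples))
    for (g in p_epi) {
      expr[g, ] <- spec$baseline +
        spec$noise_sd * (z_epi + sigma * rnorm(n))
    }
    for (g in p_stro) {
      expr[g, ] <- spec$baseline +
        spec$noise_sd * (z_stro + sigma * rnorm(n))
    }
    list(expr = expr, planted_epi = p_epi, planted_stro = p_stro,
         noise_scale = sigma)
  })
}

#' Generate a synthetic gene-set annotation
#'
#' Builds a gene-set collection over `universe`: if `planted_term_genes` is
#' given, the first term contains exactly those genes (plus optional random
#' padding up to `pad_planted_to`); the remaining terms are random subsets
#' with sizes uniform over `term_size_range`. Deterministic given `seed`.
#'
#' @param universe Character vector of gene IDs.
#' @param n_terms Total number of terms (>= 1).
#' @param term_size_range Length-2 integer range of random term sizes.
#' @param planted_term_genes Optional character vector (subset of
#'   `universe`) forming the planted term.
#' @param pad_planted_to Optional size to pad the planted term to with
#'   random extra genes.
#' @param seed Integer seed.
#' @return A named list of gene-ID vectors of class `"gene_sets"`, with a
#'   `descriptions` attribute. Write with [write_gmt()].
#' @export
generate_annotation <- function(universe, n_terms, term_size_range = c(5, 50),
                                planted_term_genes = NULL,
                                pad_planted_to = NULL, seed = 1L) {
  stopifnot(n_terms >= 1, length(term_size_range) == 2,
            term_size_range[1] >= 1,
            term_size_range[1] <= term_size_range[2])
  if (term_size_range[2] > length(universe)) {
    stop("term size range exceeds the universe size")
  }
  if (!is.null(planted_term_genes) &&
      !all(planted_term_genes %in% universe)) {
    stop("planted genes must be a subset of the universe")
  }
  with_seed(seed, {
    sets <- list()
    desc <- character(0)
    if (!is.null(planted_term_genes)) {
      g <- planted_term_genes
      if (!is.null(pad_planted_to) && pad_planted_to > length(g)) {
        g <- c(g, sample(setdiff(universe, g), pad_planted_to - length(g)))
      }
      sets[["PLANTED"]] <- g
      desc <- "planted ratio-associated term"
    }
    n_rand <- n_terms - length(sets)
    if (n_rand > 0) {
      sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                      n_rand, replace = TRUE)
      for (i in seq_len(n_rand)) {
        nm <- sprintf("T%04d", i)
        sets[[nm]] <- sample(universe, sizes[i])
        desc <- c(desc, sprintf("random term %d", i))
      }
    }
    structure(sets, descriptions = stats::setNames(desc, names(sets)),
              class = "gene_sets")
  })
}
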