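# Internal helpers shared across modules.

# Run `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Validate an H x W x 3 numeric raster with 8-bit RGB semantics (0..255).
check_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img)) {
    stop(what, " must be a numeric H x W x 3 array", call. = FALSE)
  }
  invisible(img)
}

# Validate an integer-valued label mask with codes in `codes`.
check_mask <- function(mask, codes = 0:2, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (!all(mask %in% codes)) {
    stop(what, " has labels outside {", paste(codes, collapse = ","), "}",
         call. = FALSE)
  }
  invisible(mask)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
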