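# Shared fixtures, built in code at test time.

# A small slide with a planted ellipse, cheap enough for unit tests.
small_slide <- function(seed = 1, epi = 0.6, w = 564, h = 360) {
  generate_slide(slide_spec(w, h, epi_fraction_target = epi, seed = seed))
}

# Bounding box (0-based, half-open) of the nonzero region of a mask.
mask_bbox <- function(mask) {
  r <- which(rowSums(mask > 0) > 0)
  cc <- which(colSums(mask > 0) > 0)
  c(min(r) - 1, max(r), min(cc) - 1, max(cc))
}

bbox_iou <- function(a, b) {
  ih <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[3], b[3]))
  inter <- ih * iw
  union <- (a[2] - a[1]) * (a[4] - a[3]) + (b[2] - b[1]) * (b[4] - b[3]) -
    inter
  inter / union
}

roi_as_bbox <- function(roi) {
  c(roi$row_start, roi$row_end, roi$col_start, roi$col_end)
}

# Independent brute-force Eq.-style 1-D dilated convolution (double loop).
brute_dilated_1d <- function(x, w, rate) {
  n_out <- length(x) - rate * length(w)
  y <- numeric(n_out)
  for (i in seq_len(n_out)) {
    acc <- 0
    for (k in seq_along(w)) acc <- acc + x[i + rate * k] * w[k]
    y[i] <- acc
  }
  y
}

# Independent brute-force centered zero-padded 2-D dilated convolution.
brute_dilated_2d <- function(f, kernel, rate) {
  k <- nrow(kernel)
  half <- (k - 1) %/% 2
  out <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(f))) {
      acc <- 0
      for (ki in seq_len(k)) {
        for (kj in seq_len(k)) {
          ii <- i + (ki - 1 - half) * rate
          jj <- j + (kj - 1 - half) * rate
          if (ii >= 1 && ii <= nrow(f) && jj >= 1 && jj <= ncol(f)) {
            acc <- acc + f[ii, jj] * kernel[ki, kj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Independent hypergeometric upper tail by exhaustive enumeration over all
# C(N, n) selections (feasible for N <= 12).
enum_hyper_tail <- function(k, K, N, n) {
  sel <- utils::combn(N, n)
  in_term <- seq_len(K)
  hits <- colSums(matrix(sel %in% in_term, nrow = n))
  mean(hits >= k)
}
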