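# Tissue quantification from stitched masks and the confusion-matrix
# metric suite used to evaluate segmentations.

#' Count tissue pixels in a patch mask
#'
#' @param mask Label matrix (0 = background, 1 = epithelium, 2 = stroma).
#' @return List with `Ti` (tissue = epithelial + stromal), `Ei`, `Si`.
#' @export
count_patch <- function(mask) {
  check_mask(mask)
  Ei <- sum(mask == 1L)
  Si <- sum(mask == 2L)
  list(Ti = Ei + Si, Ei = Ei, Si = Si)
}

#' Epithelial and stromal tissue ratios
#'
#' Pools pixel counts over the valid patches and returns
#' `ratio_epi = sum(Ei) / sum(Ti)` and `ratio_stro = sum(Si) / sum(Ti)`.
#' Because tissue is defined as epithelium plus stroma, the two ratios sum
#' to 1 whenever any tissue is present.
#'
#' @param counts List of [count_patch()] results (possibly from many
#'   patches).
#' @return Object of class `"tissue_ratios"`: list with `ratio_epi`,
#'   `ratio_stro`.
#' @export
compute_ratios <- function(counts) {
  if (length(counts) > 0 && !is.null(counts$Ti)) counts <- list(counts)
  sT <- sum(vapply(counts, `[[`, numeric(1), "Ti"))
  sE <- sum(vapply(counts, `[[`, numeric(1), "Ei"))
  sS <- sum(vapply(counts, `[[`, numeric(1), "Si"))
  if (sT == 0) stop("no tissue: total tissue pixel count is zero")
  structure(list(ratio_epi = sE / sT, ratio_stro = sS / sT),
            class = "tissue_ratios")
}

#' @export
print.tissue_ratios <- function(x, ...) {
  cat(sprintf("epithelial ratio %.4f, stromal ratio %.4f\n",
              x$ratio_epi, x$ratio_stro))
  invisible(x)
}

#' Confusion counts for one tissue class
#'
#' Tallies TP/FP/TN/FN over pixels, treating `positive_label` as the
#' positive class and the other tissue label as negative; pixels where the
#' truth equals `ignore_label` (unannotated background) are excluded.
#'
#' @param pred,truth Label matrices of identical shape.
#' @param positive_label Tissue code treated as positive (1 or 2).
#' @param ignore_label Truth code excluded from scoring (default 0).
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth, positive_label, ignore_label = 0L) {
  if (!all(dim(pred) == dim(truth))) stop("pred/truth shape mismatch")
  keep <- truth != ignore_label
  p <- pred[keep] == positive_label
  t <- truth[keep] == positive_label
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t),
       FN = sum(!p & t))
}

#' Sum confusion counts across images
#' @param confs List of [confusion()] results.
#' @return Pooled confusion counts.
#' @export
pool_confusion <- function(confs) {
  list(TP = sum(vapply(confs, `[[`, numeric(1), "TP")),
       FP = sum(vapply(confs, `[[`, numeric(1), "FP")),
       TN = sum(vapply(confs, `[[`, numeric(1), "TN")),
       FN = sum(vapply(confs, `[[`, numeric(1), "FN")))
}

#' Classification metric suite from confusion counts
#'
#' The ten standard binary metrics:
#' `TPR = TP/(TP+FN)`, `TNR = TN/(FP+TN)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(FN+TN)`, `FPR = FP/(FP+TN)`, `FDR = 1 - PPV`,
#' `FNR = FN/(FN+TP)`, `ACC = (TP+TN)/total`,
#' `F1 = 2*TP/(2*TP+FP+FN)`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Values are kept at full precision on the unit scale; the print method
#' reports them x100 to two decimals. A zero denominator makes the affected
#' metric `NaN` with a warning, never silently 0.
#'
#' @param c List with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector of class `"metric_set"`.
#' @export
compute_metrics <- function(c) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(c)))
  TP <- c$TP; FP <- c$FP; TN <- c$TN; FN <- c$FN
  if (TP + FP + TN + FN == 0) stop("empty confusion counts")
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  TPR <- div(TP, TP + FN, "TPR")
  TNR <- div(TN, FP + TN, "TNR")
  PPV <- div(TP, TP + FP, "PPV")
  NPV <- div(TN, FN + TN, "NPV")
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  MCC <- if (mcc_den == 0) {
    warning("MCC undefined: zero denominator")
    NaN
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  }
  structure(c(TPR = TPR, TNR = TNR, PPV = PPV, NPV = NPV,
              FPR = if (is.nan(TNR)) NaN else 1 - TNR,
              FDR = if (is.nan(PPV)) NaN else 1 - PPV,
              FNR = if (is.nan(TPR)) NaN else 1 - TPR,
              ACC = (TP + TN) / (TP + FP + TN + FN),
              F1 = div(2 * TP, 2 * TP + FP + FN, "F1"),
              MCC = MCC),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- format(round(100 * unclass(x), 2), nsmall = 2)
  cat(paste(sprintf("%s %s", names(x), v), collapse = "  "), "\n")
  invisible(x)
}

#' Reconstruct a metric suite from reported rates
#'
#' Given TPR, TNR and PPV (percent scale, as benchmark tables report them),
#' solves for the implied class prevalence, reconstructs the normalized
#' confusion matrix, and recomputes the full metric suite. Useful for
#' internal-consistency checks of published metric tables: the recomputed
#' NPV, ACC, F1 and MCC must agree with the reported ones up to input
#' rounding.
#'
#' @param TPR,TNR,PPV Rates on the percent (0-100) scale.
#' @return A `"metric_set"` (unit scale; print reports x100).
#' @export
metrics_from_rates <- function(TPR, TNR, PPV) {
  tpr <- TPR / 100
  tnr <- TNR / 100
  ppv <- PPV / 100
  fpr <- 1 - tnr
  prev <- ppv * fpr / (tpr - tpr * ppv + ppv * fpr)
  compute_metrics(list(TP = tpr * prev, FN = (1 - tpr) * prev,
                       FP = fpr * (1 - prev), TN = tnr * (1 - prev)))
}

#' Published cohort benchmark metrics
#'
#' Percent-scale metric rows reported for a dilated-convolution
#' epithelium/stroma segmentation model on the NKI and VGH tissue
#' microarray cohorts. Shipped so the metric formulas can be checked for
#' internal consistency against published numbers (see
#' [metrics_from_rates()]).
#'
#' @return Data frame with columns `cohort`, `TPR`, `TNR`, `PPV`, `NPV`,
#'   `FPR`, `FDR`, `FNR`, `ACC`, `F1`, `MCC`, all on the percent scale.
#' @export
cohort_benchmark_metrics <- function() {
  data.frame(
    cohort = c("NKI", "VGH"),
    TPR = c(90.71, 91.37), TNR = c(89.83, 91.49), PPV = c(90.81, 92.37),
    NPV = c(89.72, 90.38), FPR = c(10.17, 8.51), FDR = c(9.19, 7.63),
    FNR = c(9.29, 8.63), ACC = c(90.29, 91.42), F1 = c(90.76, 91.87),
    MCC = c(80.54, 82.80)
  )
}
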