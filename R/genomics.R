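# Image-genomics association: Spearman correlation of per-sample tissue
# ratios with gene expression, top-fraction gene selection, and
# hypergeometric over-representation analysis of gene sets.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Constant inputs have no defined rank correlation and raise an
#' error rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for constant input")
  }
  cor(x, y, method = "spearman")
}

#' Correlate gene expression with tissue ratios
#'
#' Computes, for every gene, the Spearman correlation of its expression
#' with the epithelial ratio and with the stromal ratio across samples.
#' Sample IDs of `ratios` must match the expression columns (any order);
#' genes with constant expression get `NA` correlations and are flagged.
#'
#' @param expr Genes x samples numeric matrix with gene row names and
#'   sample column names.
#' @param ratios Data frame with columns `sample`, `ratio_epi` and
#'   (optionally) `ratio_stro`; if absent,
#'   `ratio_stro = 1 - ratio_epi`.
#' @return Data frame of class `"correlation_table"`: `gene`, `rho_epi`,
#'   `rho_stro`, `undefined`.
#' @export
correlate_expression <- function(expr, ratios) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  stopifnot(is.data.frame(ratios), all(c("sample", "ratio_epi") %in%
                                         names(ratios)))
  if (!setequal(ratios$sample, colnames(expr)) ||
      nrow(ratios) != ncol(expr)) {
    stop("sample IDs of ratios and expression matrix do not match")
  }
  ratios <- ratios[match(colnames(expr), ratios$sample), ]
  if (is.null(ratios$ratio_stro)) ratios$ratio_stro <- 1 - ratios$ratio_epi
  constant <- apply(expr, 1, function(v) sd(v) == 0)
  suppressWarnings({
    rho <- cor(t(expr), cbind(ratios$ratio_epi, ratios$ratio_stro),
               method = "spearman")
  })
  out <- data.frame(gene = rownames(expr), rho_epi = rho[, 1],
                    rho_stro = rho[, 2], undefined = constant,
                    row.names = NULL)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Select the top fraction of ratio-correlated genes
#'
#' Sorts genes by signed Spearman correlation with the chosen tissue ratio
#' (descending; optionally by absolute value) and returns the top
#' `ceiling(fraction * n_genes)`. Ties at the cut are broken by gene-ID
#' lexicographic order, so the selection is deterministic. Genes with
#' undefined correlations are excluded.
#'
#' @param table A [correlate_expression()] table.
#' @param tissue `"epi"` or `"stro"`.
#' @param fraction Selection fraction in `(0, 1]` (default 0.01, the top
#'   1 percent).
#' @param use_abs Rank by `|rho|` instead of signed rho.
#' @return Character vector of selected gene IDs.
#' @export
select_top_fraction <- function(table, tissue = c("epi", "stro"),
                                fraction = 0.01, use_abs = FALSE) {
  tissue <- match.arg(tissue)
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(table) == 0) stop("empty correlation table")
  rho <- table[[paste0("rho_", tissue)]]
  keep <- !table$undefined & is.finite(rho)
  tab <- table[keep, ]
  rho <- rho[keep]
  if (use_abs) rho <- abs(rho)
  n_sel <- ceiling(fraction * nrow(table))
  ord <- order(-rho, tab$gene)
  tab$gene[ord][seq_len(min(n_sel, nrow(tab)))]
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, counts hits `k` of the selection (size `n`)
#' in the term (size `K` after intersecting with the reference universe of
#' size `N`) and computes the hypergeometric upper-tail probability
#' `p = P(X >= k)` plus the Bonferroni-adjusted
#' `p_bonf = min(1, m * p)`, where `m` is the number of terms actually
#' tested (those with `K >= min_term_size`). The enrichment ratio is
#' `(k/n) / (K/N)`. Rows are sorted by increasing `p`.
#'
#' @param selection Character vector of selected genes (subset of
#'   `reference`).
#' @param annotation A `"gene_sets"` collection (see
#'   [generate_annotation()] / [read_gmt()]).
#' @param reference Character vector: the reference gene universe.
#' @param min_term_size Minimum in-reference term size tested (default 5).
#' @param adjust `"bonferroni"` (default) or `"BH"`; `"BH"` adds a
#'   `p_bh` column (Benjamini-Hochberg) next to `p_bonf`.
#' @return Data frame with columns `term`, `description`, `k`, `n`, `K`,
#'   `N`, `enrichment_ratio`, `p`, `p_bonf` (and optionally `p_bh`).
#' @export
ora_enrich <- function(selection, annotation, reference, min_term_size = 5L,
                       adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (length(reference) == 0) stop("empty reference universe")
  if (length(selection) == 0) stop("empty selection")
  reference <- unique(reference)
  selection <- unique(selection)
  if (!all(selection %in% reference)) {
    stop("selection must be a subset of the reference universe")
  }
  N <- length(reference)
  n <- length(selection)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(annotation[[term]], reference)
    K <- length(genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(selection, genes))
    data.frame(term = term,
               description = attr(annotation, "descriptions")[term],
               k = k, n = n, K = K, N = N,
               enrichment_ratio = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               row.names = NULL)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no term passes the minimum size filter")
  m <- nrow(rows)
  rows$p_bonf <- pmin(1, m * rows$p)
  if (adjust == "BH") rows$p_bh <- stats::p.adjust(rows$p, method = "BH")
  rows[order(rows$p, rows$term), , drop = FALSE]
}

#' Top enriched terms
#'
#' First `k` rows under the ordering (adjusted p, raw p, decreasing
#' enrichment ratio, term ID); fewer if fewer exist.
#'
#' @param rows An [ora_enrich()] result.
#' @param k Number of terms to keep (default 10).
#' @return Data frame of at most `k` rows.
#' @export
top_terms <- function(rows, k = 10L) {
  ord <- order(rows$p_bonf, rows$p, -rows$enrichment_ratio, rows$term)
  head(rows[ord, , drop = FALSE], k)
}
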