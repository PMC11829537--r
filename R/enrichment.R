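#' Differential expression by Welch's t-test on normalized log2 counts
#'
#' A deliberately simple built-in DE test: counts are scaled by
#' median-of-ratios size factors (robust to composition shifts from
#' strongly regulated genes, with a total-count fallback when no gene is
#' expressed everywhere), converted to log2(scaled count + 0.5), and each
#' gene is tested with Welch's unequal-variance t-test between the two
#' groups; p-values are Benjamini-Hochberg adjusted and log2fc is the
#' case-minus-control mean difference on the normalized log2 scale.  A
#' gene is a DEG iff `padj < alpha` and `|log2fc| > lfc_cut`.  A
#' precomputed differential-expression table (columns gene, log2fc, padj)
#' is accepted verbatim through `de_table`.
#'
#' @param counts Genes x samples count matrix (ignored when `de_table`
#'   given).
#' @param groups Character/factor vector over samples with exactly two
#'   levels; the first level encountered is treated as "case".
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_cut Absolute log2 fold-change threshold (default 1.0).
#' @param de_table Optional precomputed table used verbatim.
#' @return List with `table` (data.frame gene, log2fc, padj) and `degs`
#'   (character vector of DEG ids).
#' @export
call_degs <- function(counts = NULL, groups = NULL, alpha = 0.01,
                      lfc_cut = 1.0, de_table = NULL) {
  if (!is.null(de_table)) {
    stopifnot(all(c("gene", "log2fc", "padj") %in% names(de_table)))
    tab <- de_table
  } else {
    lv <- unique(as.character(groups))
    if (length(lv) != 2L) stop("exactly two groups are required")
    i1 <- which(groups == lv[1]); i2 <- which(groups == lv[2])
    if (length(i1) < 3L || length(i2) < 3L) stop("each group needs >= 3 samples")
    sf <- .size_factors(counts)
    x <- log2(t(t(counts) / sf) + 0.5)
    m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
    v1 <- .row_vars(x[, i1, drop = FALSE]); v2 <- .row_vars(x[, i2, drop = FALSE])
    n1 <- length(i1); n2 <- length(i2)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(tstat)] <- 1       # constant genes in both groups
    lfc <- m1 - m2
    lfc[!is.finite(tstat) & abs(lfc) < 1e-12] <- 0
    tab <- data.frame(gene = rownames(counts), log2fc = lfc,
                      padj = stats::p.adjust(p, "BH"),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  }
  degs <- tab$gene[!is.na(tab$padj) & tab$padj < alpha & abs(tab$log2fc) > lfc_cut]
  list(table = tab, degs = degs)
}

# median-of-ratios size factors (geometric-mean reference)
.size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (sum(all_pos) >= 10) {
    ref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2, function(cj) {
      exp(stats::median(log(cj) - ref))
    })
  } else {
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
  }
  sf
}

.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Hypergeometric over-representation analysis with size filtering
#'
#' One-sided upper-tail hypergeometric test of DEG over-representation in
#' each gene set, BH-adjusted across the tested sets.  Set sizes are
#' computed after intersecting with the universe; only sets with
#' `size_min <= size <= size_max` are tested, and a set is selected iff it
#' passes the size window and `padj < alpha`.
#'
#' @param deg_list Character vector of DEG ids (subset of `universe`).
#' @param universe Character vector of measured gene ids.
#' @param gene_sets Named list of character vectors.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param size_min,size_max Inclusive size window after universe
#'   intersection (defaults 6 and 499, i.e. more than five and fewer than
#'   500 genes).
#' @return List with `table` (data.frame set_id, overlap_count,
#'   set_size_in_universe, p, padj) over tested sets and `selected`
#'   (character vector).
#' @export
ora <- function(deg_list, universe, gene_sets, alpha = 0.01,
                size_min = 6, size_max = 499) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(deg_list %in% universe)) stop("deg_list must be a subset of universe")
  sizes <- vapply(gene_sets, function(s) length(intersect(s, universe)), integer(1))
  keep <- sizes >= size_min & sizes <= size_max
  tested <- gene_sets[keep]
  N <- length(universe); k <- length(deg_list)
  ov <- vapply(tested, function(s) {
    length(intersect(intersect(s, universe), deg_list))
  }, integer(1))
  m <- sizes[keep]
  # P(X >= ov) for X ~ Hypergeom(N, m, k)
  p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
  tab <- data.frame(
    set_id = names(tested), overlap_count = ov,
    set_size_in_universe = m, p = p,
    padj = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab, selected = tab$set_id[tab$padj < alpha])
}

#' Overlap coefficient between two gene sets
#'
#' `|A \[intersect\] B| / min(|A|, |B|)`; values above 0.5 indicate
#' substantial redundancy.
#'
#' @param set_a,set_b Non-empty character vectors.
#' @return Numeric scalar in `[0, 1]`.
#' @export
overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty gene set")
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Prune redundant gene sets by overlap coefficient
#'
#' Greedy scan in ascending enrichment padj (ties broken towards the
#' larger set, then lexicographic id): a set is retained iff its overlap
#' coefficient with every previously retained set is `<= threshold`.  When
#' two near-duplicates compete, the more significantly enriched member
#' survives.
#'
#' @param gene_sets Named list of character vectors.
#' @param padj Named (or parallel) numeric vector of enrichment adjusted
#'   p-values for every set.
#' @param threshold Overlap-coefficient threshold (default 0.5).
#' @return Character vector of retained set ids, in scan order.
#' @export
prune_redundant <- function(gene_sets, padj, threshold = 0.5) {
  if (is.null(names(padj))) names(padj) <- names(gene_sets)
  stopifnot(all(names(gene_sets) %in% names(padj)))
  padj <- padj[names(gene_sets)]
  sizes <- lengths(gene_sets)
  ord <- order(padj, -sizes, names(gene_sets))
  retained <- character(0)
  for (id in names(gene_sets)[ord]) {
    ok <- all(vapply(retained, function(r) {
      overlap_coefficient(gene_sets[[id]], gene_sets[[r]]) <= threshold
    }, logical(1)))
    if (ok) retained <- c(retained, id)
  }
  retained
}
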