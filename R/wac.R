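#' Label a gene set's disease regulation
#'
#' Keeps the set genes that pass both differential-expression thresholds
#' (`padj < alpha` and `|log2fc| > lfc_cut`) and labels them `"+"` for
#' upregulated, `"-"` for downregulated in disease.  Set genes absent from
#' the table are skipped with a warning.
#'
#' @param de_table Data frame with columns gene, log2fc, padj.
#' @param gene_set Character vector of gene ids.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @return Data frame with columns `gene`, `label`; zero rows when no
#'   gene passes.
#' @export
label_disease <- function(de_table, gene_set, alpha = 0.01, lfc_cut = 0.5) {
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, de_table$gene)
  if (length(missing)) {
    warning(sprintf("%d set gene(s) not covered by the DE table; skipped",
                    length(missing)))
  }
  rows <- de_table[match(setdiff(gene_set, missing), de_table$gene), ]
  pass <- !is.na(rows$padj) & rows$padj < alpha & abs(rows$log2fc) > lfc_cut
  rows <- rows[pass, , drop = FALSE]
  data.frame(gene = rows$gene,
             label = ifelse(rows$log2fc > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Label treatment regulation with sign flip
#'
#' Genes upregulated by the treatment (effect above `effect_cut`, and
#' `padj < alpha` when a significance column is available) receive label
#' `"-"`, downregulated genes `"+"` -- the sign flip encodes that reversal
#' of the disease direction counts as agreement.  Residual genes, and
#' genes missing from the profile (warned), are labelled `"0"`.
#'
#' @param profile Named numeric vector of treatment effect values (one
#'   compound), or a data frame with columns gene, effect and optionally
#'   padj.
#' @param deg_genes Character vector of the disease-labelled genes.
#' @param effect_cut Absolute effect threshold (default 0.5).
#' @param alpha Adjusted-p threshold, applied only when significance
#'   values are present (default 0.01).
#' @return Character vector of labels in `{"+", "-", "0"}` parallel to
#'   `deg_genes`.
#' @export
label_treatment <- function(profile, deg_genes, effect_cut = 0.5,
                            alpha = 0.01) {
  if (is.data.frame(profile)) {
    eff <- stats::setNames(profile$effect, profile$gene)
    sig <- if ("padj" %in% names(profile)) {
      stats::setNames(profile$padj, profile$gene)
    } else NULL
  } else {
    eff <- profile
    sig <- NULL
  }
  missing <- setdiff(deg_genes, names(eff))
  if (length(missing)) {
    warning(sprintf("%d gene(s) missing from the profile; labelled '0'",
                    length(missing)))
  }
  e <- eff[deg_genes]
  lab <- rep("0", length(deg_genes))
  up <- !is.na(e) & e > effect_cut
  dn <- !is.na(e) & e < -effect_cut
  if (!is.null(sig)) {
    s_ok <- !is.na(sig[deg_genes]) & sig[deg_genes] < alpha
    up <- up & s_ok
    dn <- dn & s_ok
  }
  lab[up] <- "-"
  lab[dn] <- "+"
  lab
}

#' Betweenness-derived gene importance weights
#'
#' `w_i = 1 + b_i` for genes present in the network (with `b_i` the
#' normalized betweenness in `[0, 1]`), and `w_i = 1` for absent genes, so
#' that a gene set entirely outside the network reduces the wAC to the
#' unweighted AC1.
#'
#' @param betweenness_map Named numeric vector of normalized betweenness.
#' @param genes Character vector of gene ids.
#' @return Named positive numeric weights parallel to `genes`.
#' @export
gene_weights <- function(betweenness_map, genes) {
  b <- betweenness_map[genes]
  b[is.na(b)] <- 0
  stats::setNames(1 + as.numeric(b), genes)
}

#' Weighted Gwet AC1 agreement between disease and treatment labels
#'
#' With subject weights `w_i` (total `W`), the observed weighted agreement
#' is `pa = sum(w_i * [a_i == b_i]) / W`; the category proportions over
#' the fixed category space `Q = {+, -, 0}` are
#' `pi_q = (sum_i w_i [a_i = q] + sum_i w_i [b_i = q]) / (2 W)`; the
#' chance agreement is `pe = sum_q pi_q (1 - pi_q) / (|Q| - 1)`; and
#' `wAC = (pa - pe) / (1 - pe)`, clipped to `[-1, 1]` (the raw value is
#' also reported).  With unit weights this is Gwet's AC1.  The disease
#' rater never uses category `"0"`, but the treatment rater does, so the
#' default category space is the full ternary one; a binary mode
#' (`|Q| = 2`, categories `{+, -}` only in `pe`) is available for
#' comparison.
#'
#' @param disease_labels Character vector in `{"+", "-"}`.
#' @param treatment_labels Character vector in `{"+", "-", "0"}`, same
#'   length.
#' @param weights Positive numeric weights (default unit).
#' @param category_space `"ternary"` (default) or `"binary"`.
#' @return List with `pa`, `pe`, `wac`, `wac_raw`, `n_genes`; all-`NA`
#'   result (with a `reason` element) for fewer than 2 labelled genes or
#'   degenerate `pe = 1`.
#' @export
wac <- function(disease_labels, treatment_labels, weights = NULL,
                category_space = c("ternary", "binary")) {
  category_space <- match.arg(category_space)
  n <- length(disease_labels)
  stopifnot(length(treatment_labels) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  na_result <- function(reason) {
    list(pa = NA_real_, pe = NA_real_, wac = NA_real_, wac_raw = NA_real_,
         n_genes = n, reason = reason)
  }
  if (n < 2L) return(na_result("fewer than 2 labelled genes"))
  W <- sum(weights)
  pa <- sum(weights * (disease_labels == treatment_labels)) / W
  cats <- if (category_space == "ternary") c("+", "-", "0") else c("+", "-")
  pi_q <- vapply(cats, function(q) {
    (sum(weights * (disease_labels == q)) +
       sum(weights * (treatment_labels == q))) / (2 * W)
  }, numeric(1))
  pe <- sum(pi_q * (1 - pi_q)) / (length(cats) - 1)
  if (1 - pe < 1e-12) return(na_result("degenerate expected agreement pe = 1"))
  raw <- (pa - pe) / (1 - pe)
  list(pa = pa, pe = pe, wac = min(1, max(-1, raw)), wac_raw = raw,
       n_genes = n, reason = NA_character_)
}

#' Compute the compounds x gene-sets wAC table
#'
#' Applies [label_disease()] once per gene set, then [label_treatment()]
#' and [wac()] for every (compound, set) cell, using betweenness-derived
#' gene weights.  Cells with no usable DEGs are recorded as missing, never
#' imputed.
#'
#' @param profiles Genes x compounds numeric matrix of treatment effects.
#' @param de_table Differential-expression table (gene, log2fc, padj).
#' @param gene_sets Named list of character vectors.
#' @param betweenness_map Named normalized betweenness vector (`NULL` for
#'   unit weights).
#' @param alpha,lfc_cut Disease labelling thresholds (defaults 0.01, 0.5).
#' @param effect_cut Treatment labelling threshold (default 0.5).
#' @param category_space Passed to [wac()].
#' @return Long-format data frame with columns compound, set_id, pa, pe,
#'   wac, n_genes.
#' @export
wac_matrix <- function(profiles, de_table, gene_sets, betweenness_map = NULL,
                       alpha = 0.01, lfc_cut = 0.5, effect_cut = 0.5,
                       category_space = c("ternary", "binary")) {
  category_space <- match.arg(category_space)
  compounds <- colnames(profiles)
  out <- vector("list", length(gene_sets))
  n_cat <- if (category_space == "ternary") 3L else 2L
  for (si in seq_along(gene_sets)) {
    set_id <- names(gene_sets)[si]
    lab <- suppressWarnings(
      label_disease(de_table, gene_sets[[si]], alpha = alpha, lfc_cut = lfc_cut)
    )
    n_g <- nrow(lab)
    if (n_g < 2L) {
      out[[si]] <- data.frame(compound = compounds, set_id = set_id,
                              pa = NA_real_, pe = NA_real_, wac = NA_real_,
                              n_genes = n_g, stringsAsFactors = FALSE)
      next
    }
    w <- if (is.null(betweenness_map)) {
      rep(1, n_g)
    } else {
      gene_weights(betweenness_map, lab$gene)
    }
    W <- sum(w)
    present <- lab$gene %in% rownames(profiles)
    eff <- matrix(0, nrow = n_g, ncol = length(compounds))
    eff[present, ] <- profiles[lab$gene[present], , drop = FALSE]
    # sign-flipped treatment labels: up -> "-", down -> "+", residual "0"
    tl_plus <- eff < -effect_cut
    tl_minus <- eff > effect_cut
    a_plus <- lab$label == "+"
    pa <- (colSums(w * (tl_plus & a_plus)) + colSums(w * (tl_minus & !a_plus))) / W
    wa_plus <- sum(w * a_plus); wa_minus <- W - wa_plus
    pi_plus <- (wa_plus + colSums(w * tl_plus)) / (2 * W)
    pi_minus <- (wa_minus + colSums(w * tl_minus)) / (2 * W)
    pi_zero <- colSums(w * (!tl_plus & !tl_minus)) / (2 * W)
    pe <- if (n_cat == 3L) {
      (pi_plus * (1 - pi_plus) + pi_minus * (1 - pi_minus) +
         pi_zero * (1 - pi_zero)) / 2
    } else {
      pi_plus * (1 - pi_plus) + pi_minus * (1 - pi_minus)
    }
    wac_val <- ifelse(1 - pe < 1e-12, NA_real_,
                      pmin(1, pmax(-1, (pa - pe) / (1 - pe))))
    out[[si]] <- data.frame(compound = compounds, set_id = set_id,
                            pa = pa, pe = pe, wac = wac_val, n_genes = n_g,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape a long wAC table to a compounds x sets matrix
#'
#' @param wac_long Output of [wac_matrix()].
#' @return Numeric matrix, compounds in rows, set ids in columns.
#' @export
wac_to_matrix <- function(wac_long) {
  compounds <- unique(wac_long$compound)
  sets <- unique(wac_long$set_id)
  m <- matrix(NA_real_, nrow = length(compounds), ncol = length(sets),
              dimnames = list(compounds, sets))
  m[cbind(match(wac_long$compound, compounds),
          match(wac_long$set_id, sets))] <- wac_long$wac
  m
}
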