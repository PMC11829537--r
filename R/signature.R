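#' One-sided Wilcoxon comparison of wAC between positive and negative drugs
#'
#' For every gene set, tests whether the disease (positive) drugs have
#' stochastically greater wAC values than the remaining (negative)
#' compounds, with `wilcox.test(alternative = "greater")`: the exact rank
#' distribution when both groups have at most `exact_max` non-missing
#' values and no ties, the tie-corrected normal approximation otherwise.
#'
#' @param wac_mat Compounds x sets wAC matrix ([wac_to_matrix()]).
#' @param positive_ids Character vector of positive compound ids.
#' @param min_group Minimum non-missing compounds per group (default 3).
#' @param exact_max Largest group size for the exact distribution
#'   (default 10).
#' @return Data frame with columns set_id, wilcoxon_p (NA when either
#'   group is too small).
#' @export
compare_groups <- function(wac_mat, positive_ids, min_group = 3,
                           exact_max = 10) {
  pos <- intersect(rownames(wac_mat), positive_ids)
  neg <- setdiff(rownames(wac_mat), positive_ids)
  if (length(pos) == 0L) stop("empty positive group")
  p <- vapply(colnames(wac_mat), function(s) {
    x <- wac_mat[pos, s]; x <- x[!is.na(x)]
    y <- wac_mat[neg, s]; y <- y[!is.na(y)]
    if (length(x) < min_group || length(y) < min_group) return(NA_real_)
    use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = use_exact,
                         correct = !use_exact)$p.value
    )
  }, numeric(1))
  data.frame(set_id = colnames(wac_mat), wilcoxon_p = p,
             stringsAsFactors = FALSE)
}

#' Correlation of wAC with drug sensitivity per panel
#'
#' Pearson correlation (two-sided p from the t transform) between each
#' gene set's wAC values and ln(IC50) across the compounds shared with
#' each sensitivity panel.  A negative correlation means stronger reversal
#' goes with greater sensitivity.
#'
#' @param wac_mat Compounds x sets wAC matrix.
#' @param panels Named list of data frames with columns compound,
#'   ln_ic50.
#' @param min_overlap Minimum shared compounds per panel (default 5).
#' @return Data frame with columns set_id, panel, pearson_r, pearson_p
#'   (NA for insufficient overlap or zero variance).
#' @export
sensitivity_correlation <- function(wac_mat, panels, min_overlap = 5) {
  if (is.null(names(panels))) names(panels) <- paste0("panel", seq_along(panels))
  out <- lapply(names(panels), function(pn) {
    panel <- panels[[pn]]
    shared <- intersect(rownames(wac_mat), panel$compound)
    ic50 <- panel$ln_ic50[match(shared, panel$compound)]
    res <- t(vapply(colnames(wac_mat), function(s) {
      x <- wac_mat[shared, s]
      ok <- !is.na(x) & !is.na(ic50)
      if (sum(ok) < min_overlap) return(c(NA_real_, NA_real_))
      if (stats::sd(x[ok]) == 0 || stats::sd(ic50[ok]) == 0) {
        return(c(NA_real_, NA_real_))
      }
      ct <- stats::cor.test(x[ok], ic50[ok], method = "pearson")
      c(ct$estimate, ct$p.value)
    }, numeric(2)))
    data.frame(set_id = colnames(wac_mat), panel = pn,
               pearson_r = res[, 1], pearson_p = res[, 2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select signature gene sets
#'
#' A set is a signature iff (a) its wAC is significantly higher among
#' positive drugs (`wilcoxon_p < alpha`) and (b) it is negatively
#' correlated with ln(IC50) (`pearson_r < 0` and `pearson_p < alpha`) in
#' the required sensitivity panels (`panel_rule = "any"` or `"all"`).
#' Raw p-values are used by default, matching the stated significance
#' rule; set `adjust = "BH"` for a multiplicity-corrected variant.
#'
#' @param wilcoxon_table Output of [compare_groups()].
#' @param correlation_table Output of [sensitivity_correlation()].
#' @param alpha Significance threshold (default 0.01).
#' @param panel_rule `"any"` (default) or `"all"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `verdicts` (per-set data frame with `selected` flag)
#'   and `selected` (character vector of signature set ids).
#' @export
select_signature <- function(wilcoxon_table, correlation_table, alpha = 0.01,
                             panel_rule = c("any", "all"),
                             adjust = c("none", "BH")) {
  panel_rule <- match.arg(panel_rule)
  adjust <- match.arg(adjust)
  wp <- wilcoxon_table$wilcoxon_p
  cp <- correlation_table$pearson_p
  if (adjust == "BH") {
    wp <- stats::p.adjust(wp, "BH")
    cp <- stats::p.adjust(cp, "BH")
  }
  corr_ok <- !is.na(cp) & cp < alpha &
    !is.na(correlation_table$pearson_r) & correlation_table$pearson_r < 0
  agg <- tapply(corr_ok, correlation_table$set_id,
                if (panel_rule == "any") any else all)
  verdicts <- data.frame(
    set_id = wilcoxon_table$set_id,
    wilcoxon_p = wp,
    corr_ok = as.logical(agg[wilcoxon_table$set_id]),
    stringsAsFactors = FALSE
  )
  verdicts$selected <- !is.na(verdicts$wilcoxon_p) &
    verdicts$wilcoxon_p < alpha &
    !is.na(verdicts$corr_ok) & verdicts$corr_ok
  list(verdicts = verdicts, selected = verdicts$set_id[verdicts$selected])
}
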