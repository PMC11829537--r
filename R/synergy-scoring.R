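#' Reference quantiles of positive-drug wAC values per gene set
#'
#' 50th and 80th linear-interpolation (type-7) quantiles of the positive
#' cohort's wAC values for each signature set; these define the grading
#' intervals for candidate compounds.
#'
#' @param wac_mat Compounds x sets wAC matrix.
#' @param positive_ids Positive compound ids (`>= min_n` non-missing
#'   values required per set).
#' @param min_n Minimum number of positive values (default 5).
#' @return Data frame with columns set_id, q50, q80.
#' @export
reference_quantiles <- function(wac_mat, positive_ids, min_n = 5) {
  pos <- intersect(rownames(wac_mat), positive_ids)
  qs <- t(vapply(colnames(wac_mat), function(s) {
    x <- wac_mat[pos, s]; x <- x[!is.na(x)]
    if (length(x) < min_n) {
      stop(sprintf("set %s: fewer than %d positive wAC values", s, min_n))
    }
    stats::quantile(x, c(0.5, 0.8), type = 7, names = FALSE)
  }, numeric(2)))
  data.frame(set_id = colnames(wac_mat), q50 = qs[, 1], q80 = qs[, 2],
             stringsAsFactors = FALSE)
}

#' Grade a wAC value against reference quantiles
#'
#' Three intervals from the positive-drug reference distribution:
#' below the 50th quantile is weak (0), from the 50th up to (excluding)
#' the 80th is moderate (0.5), and at or above the 80th is strong (1).
#' Interval boundaries are closed upward (`wac == q80` grades 1).  A
#' missing wAC grades 0: no measured reversal is no evidence of effect.
#'
#' @param wac_value Numeric (vectorised).
#' @param q50,q80 Reference quantiles.
#' @return Numeric grade(s) in `{0, 0.5, 1}`.
#' @export
grade <- function(wac_value, q50, q80) {
  g <- ifelse(is.na(wac_value) | wac_value < q50, 0,
              ifelse(wac_value < q80, 0.5, 1))
  as.numeric(g)
}

#' Build the compounds x signature-sets grade matrix
#'
#' @param wac_mat Compounds x sets wAC matrix (candidate compounds).
#' @param quantiles Data frame from [reference_quantiles()].
#' @return Numeric matrix of grades with the quantiles kept in the
#'   `"quantiles"` attribute.
#' @export
grade_matrix <- function(wac_mat, quantiles) {
  sets <- intersect(colnames(wac_mat), quantiles$set_id)
  gm <- vapply(sets, function(s) {
    q <- quantiles[quantiles$set_id == s, ]
    grade(wac_mat[, s], q$q50, q$q80)
  }, numeric(nrow(wac_mat)))
  gm <- matrix(gm, nrow = nrow(wac_mat),
               dimnames = list(rownames(wac_mat), sets))
  attr(gm, "quantiles") <- quantiles[match(sets, quantiles$set_id), ]
  gm
}

#' Per-compound regulation score (PS)
#'
#' Sum of the compound's grades over all signature gene sets.
#'
#' @param grades Numeric vector of grades in `{0, 0.5, 1}`.
#' @return Numeric scalar.
#' @export
ps <- function(grades) {
  sum(grades)
}

#' Two-compound combination score (TCS)
#'
#' Per signature set, the two compounds' grades are summed and capped at
#' 1; the capped sums are aggregated over all sets.  Symmetric in its
#' arguments and bounded by the number of sets.
#'
#' @param grades_a,grades_b Equal-length grade vectors.
#' @return Numeric scalar.
#' @export
tcs <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b)) {
    stop("grade vectors must have equal length")
  }
  sum(pmin(grades_a + grades_b, 1))
}

#' Enumerate and rank candidate compound pairs by TCS
#'
#' Restricts to compounds with `PS > 0`, enumerates all unordered pairs,
#' keeps those with `TCS` strictly above the threshold (default
#' `n_sets - 1`), and ranks by TCS descending, ties by `ps_a + ps_b`
#' descending, then by lexicographic pair id.  The number of eligible
#' compounds and of evaluated pairs are attached as attributes.
#'
#' @param gm Compounds x signature-sets grade matrix.
#' @param tcs_threshold Strict lower TCS bound; default `ncol(gm) - 1`.
#' @param min_ps Strict lower PS bound for eligibility (default 0).
#' @return Data frame (compound_a, compound_b, tcs, ps_a, ps_b) of
#'   passing pairs in rank order, with attributes `n_eligible` and
#'   `n_evaluated`.
#' @export
rank_candidates <- function(gm, tcs_threshold = NULL, min_ps = 0) {
  if (is.null(tcs_threshold)) tcs_threshold <- ncol(gm) - 1
  ps_all <- rowSums(gm)
  eligible <- names(ps_all)[ps_all > min_ps]
  n_eval <- if (length(eligible) >= 2L) choose(length(eligible), 2L) else 0
  if (length(eligible) < 2L) {
    out <- data.frame(compound_a = character(0), compound_b = character(0),
                      tcs = numeric(0), ps_a = numeric(0), ps_b = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_eligible") <- length(eligible)
    attr(out, "n_evaluated") <- n_eval
    return(out)
  }
  pairs <- t(utils::combn(sort(eligible), 2L))
  sub <- gm[eligible, , drop = FALSE]
  tcs_vals <- vapply(seq_len(nrow(pairs)), function(i) {
    tcs(sub[pairs[i, 1], ], sub[pairs[i, 2], ])
  }, numeric(1))
  out <- data.frame(compound_a = pairs[, 1], compound_b = pairs[, 2],
                    tcs = tcs_vals,
                    ps_a = ps_all[pairs[, 1]], ps_b = ps_all[pairs[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[out$tcs > tcs_threshold, , drop = FALSE]
  ord <- order(-out$tcs, -(out$ps_a + out$ps_b),
               out$compound_a, out$compound_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_eligible") <- length(eligible)
  attr(out, "n_evaluated") <- n_eval
  out
}
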