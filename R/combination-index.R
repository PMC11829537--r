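#' Fit the Chou-Talalay median-effect model
#'
#' Least-squares line of `log10(fa / (1 - fa))` on `log10(dose)`:
#' the slope is the shape parameter `m` and the median-effect dose is
#' `Dm = 10^(-intercept / m)`.  Affected fractions are clipped to
#' `[0.005, 0.995]` (with a warning) to keep the log-odds finite.
#'
#' @param doses Positive dose vector.
#' @param affected_fractions Fractions affected in `[0, 1]`, parallel to
#'   `doses`.
#' @param clip Length-2 clipping bounds (default `c(0.005, 0.995)`).
#' @return Object of class `"median_effect_fit"`: list with `m`, `dm`,
#'   `r2`, `n_points`.
#' @export
fit_median_effect <- function(doses, affected_fractions,
                              clip = c(0.005, 0.995)) {
  stopifnot(length(doses) == length(affected_fractions))
  if (any(doses <= 0)) stop("doses must be positive")
  fa <- affected_fractions
  if (any(fa < clip[1] | fa > clip[2])) {
    warning(sprintf("affected fractions clipped to [%g, %g]", clip[1], clip[2]))
    fa <- pmin(clip[2], pmax(clip[1], fa))
  }
  ok <- is.finite(fa) & is.finite(doses)
  if (sum(ok) < 3L) stop("fewer than 3 valid dose-response points")
  x <- log10(doses[ok])
  yv <- log10(fa[ok] / (1 - fa[ok]))
  fit <- stats::lm(yv ~ x)
  m <- unname(stats::coef(fit)[2])
  if (is.na(m) || m <= 0) stop("non-monotone response: median-effect slope m <= 0")
  dm <- 10^(-unname(stats::coef(fit)[1]) / m)
  # noise-free curves trip lm's perfect-fit warning; the fit is valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(m = m, dm = dm, r2 = r2,
                 n_points = sum(ok)),
            class = "median_effect_fit")
}

#' Chou-Talalay combination index
#'
#' At the observed combination effect level `fa_combo`, the dose of each
#' single agent that alone produces that effect is
#' `Dx_i = dm_i * (fa / (1 - fa))^(1 / m_i)`, and
#' `CI = d1 / Dx1 + d2 / Dx2`.  `CI < 1` is synergistic, `CI = 1`
#' additive, `CI > 1` antagonistic.
#'
#' @param d1,d2 Doses of the two agents in the combination.
#' @param fit1,fit2 `"median_effect_fit"` objects for the single agents.
#' @param fa_combo Observed fraction affected of the combination, in
#'   (0, 1).
#' @param clip Clipping bounds matching [fit_median_effect()]; a value at
#'   the boundary attaches a warning flag to the result.
#' @return List with `ci`, `verdict`, `dx1`, `dx2`, `clipped`.
#' @export
combination_ci <- function(d1, d2, fit1, fit2, fa_combo,
                           clip = c(0.005, 0.995)) {
  stopifnot(inherits(fit1, "median_effect_fit"),
            inherits(fit2, "median_effect_fit"))
  if (fa_combo <= 0 || fa_combo >= 1) stop("fa_combo must be in (0, 1)")
  clipped <- fa_combo <= clip[1] || fa_combo >= clip[2]
  if (clipped) {
    warning("fa_combo at the clipping boundary; CI is extrapolated")
    fa_combo <- min(clip[2], max(clip[1], fa_combo))
  }
  odds <- fa_combo / (1 - fa_combo)
  dx1 <- fit1$dm * odds^(1 / fit1$m)
  dx2 <- fit2$dm * odds^(1 / fit2$m)
  ci <- d1 / dx1 + d2 / dx2
  verdict <- if (abs(ci - 1) < 1e-9) "additive"
             else if (ci < 1) "synergistic" else "antagonistic"
  list(ci = ci, verdict = verdict, dx1 = dx1, dx2 = dx2, clipped = clipped)
}

#' Combination-index table over a dose grid
#'
#' Applies [combination_ci()] row-wise to a viability table, as used for
#' checkerboard experiments.
#'
#' @param combo Data frame with columns dose_a, dose_b,
#'   fraction_affected.
#' @param fit_a,fit_b Single-agent median-effect fits.
#' @return The input with `ci` and `verdict` columns appended.
#' @export
ci_table <- function(combo, fit_a, fit_b) {
  res <- lapply(seq_len(nrow(combo)), function(i) {
    suppressWarnings(
      combination_ci(combo$dose_a[i], combo$dose_b[i], fit_a, fit_b,
                     combo$fraction_affected[i])
    )
  })
  combo$ci <- vapply(res, `[[`, numeric(1), "ci")
  combo$verdict <- vapply(res, `[[`, character(1), "verdict")
  combo
}
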