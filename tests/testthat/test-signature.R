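make_wac_mat <- function(values, sets = "S1") {
  matrix(values, ncol = length(sets),
         dimnames = list(sprintf("C%02d", seq_len(length(values) / length(sets))),
                         sets))
}

test_that("one-sided Wilcoxon comparison matches the exact distribution", {
  wm <- make_wac_mat(c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3))
  res <- compare_groups(wm, positive_ids = c("C01", "C02", "C03"))
  expect_equal(res$wilcoxon_p, 1 / 20)  # extreme assignment of C(6,3) splits

  # identical groups are never significant
  same <- make_wac_mat(rep(c(0.5, 0.5), 3))
  res_same <- compare_groups(same, positive_ids = c("C01", "C03", "C05"))
  expect_gte(res_same$wilcoxon_p, 0.5)

  expect_error(compare_groups(wm, positive_ids = character(0)), "positive")
})

test_that("exact Wilcoxon mode agrees with full enumeration", {
  set.seed(17)
  for (rep in 1:10) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    v <- sample(stats::runif(50), nx + ny)  # tie-free
    wm <- make_wac_mat(v)
    pos <- rownames(wm)[seq_len(nx)]
    res <- compare_groups(wm, pos)
    expect_equal(res$wilcoxon_p, wilcox_enum_oracle(v[seq_len(nx)],
                                                    v[-seq_len(nx)]),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity correlation detects exact and null relations", {
  wm <- make_wac_mat(seq(0, 1, length.out = 20))
  panel_exact <- data.frame(compound = rownames(wm), ln_ic50 = -wm[, 1])
  res <- sensitivity_correlation(wm, list(sens = panel_exact))
  expect_equal(unname(res$pearson_r), -1, tolerance = 1e-12)

  # independent noise rarely looks correlated
  n_ok <- 0
  for (s in 1:100) {
    set.seed(s)
    wmn <- make_wac_mat(stats::rnorm(100))
    pn <- data.frame(compound = rownames(wmn), ln_ic50 = stats::rnorm(100))
    r <- sensitivity_correlation(wmn, list(p = pn))$pearson_r
    if (abs(r) < 0.3) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 99)

  # zero variance gives a missing result
  flat <- make_wac_mat(rep(0.4, 10))
  pf <- data.frame(compound = rownames(flat), ln_ic50 = stats::rnorm(10))
  expect_true(is.na(sensitivity_correlation(flat, list(p = pf))$pearson_r))
})

test_that("generator-coupled panels give planted sets negative correlations", {
  universe <- sprintf("G%04d", 1:200)
  expr <- generate_expression_study(universe, 5, 5, 0.3, 3, 0.2, seed = 41)
  pan <- generate_perturbation_panel(universe, expr$truth, 40, 40, c(0, 1),
                                     1.0, seed = 42)
  de_tab <- data.frame(gene = expr$truth$gene,
                       log2fc = expr$truth$sign * expr$truth$lfc,
                       padj = 0.0001)
  wl <- wac_matrix(pan$profiles, de_tab, list(S = expr$truth$gene[1:25]))
  wm <- wac_to_matrix(wl)
  sens <- generate_sensitivity(pan$strengths, 3, 4, 0.3, seed = 43)
  res <- sensitivity_correlation(wm, list(sens1 = sens))
  expect_lt(res$pearson_r, 0)
  expect_lt(res$pearson_p, 0.01)
})

test_that("signature selection recovers planted sets and honours the panel rule", {
  universe <- sprintf("G%04d", 1:400)
  expr <- generate_expression_study(universe, 10, 10, 0.3, 3, 0.2, seed = 51)
  pan <- generate_perturbation_panel(universe, expr$truth, 40, 10,
                                     c(0.4, 1), 1.0, seed = 52)
  de_tab <- data.frame(gene = expr$truth$gene,
                       log2fc = expr$truth$sign * expr$truth$lfc,
                       padj = 0.0001)
  set.seed(53)
  planted <- list(P1 = sample(expr$truth$gene, 20),
                  P2 = sample(expr$truth$gene, 25),
                  P3 = sample(expr$truth$gene, 30))
  non_deg <- setdiff(universe, expr$truth$gene)
  decoys <- stats::setNames(
    lapply(1:20, function(i) sample(non_deg, 20)),
    sprintf("DECOY%02d", 1:20)
  )
  wl <- wac_matrix(pan$profiles, de_tab, c(planted, decoys))
  wm <- wac_to_matrix(wl)
  sens <- list(sens1 = generate_sensitivity(pan$strengths, 3, 4, 0.3, 54),
               sens2 = generate_sensitivity(pan$strengths, 3, 4, 0.3, 55))
  wil <- compare_groups(wm, pan$positives)
  corr <- sensitivity_correlation(wm, sens)
  sel_any <- select_signature(wil, corr, panel_rule = "any")
  expect_setequal(sel_any$selected, c("P1", "P2", "P3"))

  sel_all <- select_signature(wil, corr, panel_rule = "all")
  expect_true(all(sel_all$selected %in% sel_any$selected))
})

test_that("selection is monotone in the positive group's evidence", {
  wm <- make_wac_mat(c(0.6, 0.55, 0.5, 0.45, 0.1, 0.15, 0.05, 0.12,
                       0.08, 0.02, 0.11, 0.03))
  pos <- c("C01", "C02", "C03", "C04")
  sens <- data.frame(compound = rownames(wm),
                     ln_ic50 = 3 - 4 * wm[, 1] + 0.01 * seq_len(12))
  base <- select_signature(compare_groups(wm, pos),
                           sensitivity_correlation(wm, list(p = sens)))
  expect_true("S1" %in% base$selected)
  wm_up <- wm
  wm_up[pos, 1] <- wm_up[pos, 1] + 0.2
  up <- select_signature(compare_groups(wm_up, pos),
                         sensitivity_correlation(wm_up, list(p = sens)))
  expect_true("S1" %in% up$selected)
})
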