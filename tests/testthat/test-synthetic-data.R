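test_that("preferential-attachment network has the expected size and is reproducible", {
  net <- generate_network(10, 2, 2, seed = 1)
  expect_equal(igraph::ecount(net$network), 16)  # (n - m) * m
  expect_equal(igraph::vcount(net$network), 10)
  expect_true(igraph::is_connected(net$network))
  expect_true(igraph::is_simple(net$network))
  expect_length(net$targets, 2)

  tree <- generate_network(3, 1, 1, seed = 0)
  expect_equal(igraph::ecount(tree$network), 2)

  a <- generate_network(50, 3, 5, seed = 7)
  b <- generate_network(50, 3, 5, seed = 7)
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(a$targets, b$targets)

  expect_error(generate_network(3, 3, 1, seed = 1), "attach_edges")
  expect_error(generate_network(10, 2, 10, seed = 1), "n_targets")
})

test_that("generated gene sets respect the size window and plant redundancy", {
  universe <- sprintf("G%04d", 1:400)
  gs <- generate_genesets(universe, n_sets = 20, size_range = c(6, 40),
                          n_planted = 3, n_redundant_pairs = 4,
                          targets = universe[1:20], seed = 3)
  expect_true(all(lengths(gs$gene_sets) >= 6 & lengths(gs$gene_sets) <= 40))
  expect_length(gs$truth$planted_module_ids, 3)
  expect_equal(nrow(gs$truth$redundant_pairs), 4)
  for (i in seq_len(nrow(gs$truth$redundant_pairs))) {
    oc <- overlap_coefficient(gs$gene_sets[[gs$truth$redundant_pairs$set_a[i]]],
                              gs$gene_sets[[gs$truth$redundant_pairs$set_b[i]]])
    expect_gt(oc, 0.5)
  }

  none <- generate_genesets(universe, 5, c(6, 20), n_planted = 0,
                            n_redundant_pairs = 0, targets = universe[1:5],
                            seed = 1)
  expect_length(none$truth$planted_module_ids, 0)

  expect_error(generate_genesets(universe[1:10], 5, c(6, 20), 0, 0,
                                 universe[1:2], seed = 1), "universe")
  expect_error(generate_genesets(universe, 5, c(3, 20), 0, 0,
                                 universe[1:2], seed = 1), "size_range")
})

test_that("a resampled near-duplicate of a 10-gene set has overlap coefficient 0.7", {
  base <- sprintf("g%02d", 1:10)
  partner <- c(base[1:7], "x1", "x2", "x3")  # 3 of 10 genes resampled
  expect_equal(overlap_coefficient(base, partner), 0.7)
})

test_that("expression study is reproducible and powered as designed", {
  universe <- sprintf("G%04d", 1:500)
  a <- generate_expression_study(universe, 10, 10, 0.2, 3, 0.2, seed = 5)
  b <- generate_expression_study(universe, 10, 10, 0.2, 3, 0.2, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(dim(a$counts), c(500, 20))

  # planted DEGs at lfc 3 are recovered at the (0.01, 1.0) thresholds
  big <- generate_expression_study(universe, 20, 20, 0.2, 3, 0.2, seed = 11)
  de <- call_degs(big$counts, big$groups, alpha = 0.01, lfc_cut = 1.0)
  recovered <- mean(big$truth$gene %in% de$degs)
  expect_gte(recovered, 0.9)

  expect_error(generate_expression_study(universe, 2, 10, 0.2, 3, 0.2, 1),
               ">= 3 samples")
})

test_that("null expression study yields a controlled false-positive rate", {
  universe <- sprintf("G%04d", 1:2000)
  nullstudy <- generate_expression_study(universe, 10, 10, 0, 3, 0.2, seed = 21)
  expect_equal(nrow(nullstudy$truth), 0)
  de <- call_degs(nullstudy$counts, nullstudy$groups, alpha = 0.01, lfc_cut = 1.0)
  expect_lte(length(de$degs) / 2000, 0.05)
})

test_that("perturbation panel plants exact reversers and graded strengths", {
  universe <- sprintf("G%04d", 1:200)
  expr <- generate_expression_study(universe, 5, 5, 0.3, 3, 0.2, seed = 2)
  # strength 1, zero noise: treatment labels are the exact flip
  p <- generate_perturbation_panel(universe, expr$truth, 3, 1, c(1, 1), 0,
                                   seed = 4)
  disease <- ifelse(expr$truth$sign > 0, "+", "-")
  treatment <- label_treatment(p$profiles[, p$positives[1]], expr$truth$gene)
  expect_identical(treatment, disease)

  expect_error(generate_perturbation_panel(universe, expr$truth[0, ], 3, 1,
                                           c(1, 1), 0, seed = 1), "DEG")
})

test_that("wAC on planted sets is null-centred without positives and monotone in strength", {
  universe <- sprintf("G%04d", 1:200)
  expr <- generate_expression_study(universe, 10, 10, 0.3, 3, 0.2, seed = 8)
  de <- call_degs(expr$counts, expr$groups)
  planted_set <- list(PS = expr$truth$gene[1:25])

  # no positives: mean wAC across 200 noise compounds is near zero
  nullp <- generate_perturbation_panel(universe, expr$truth, 200, 0, c(0, 0),
                                       1.0, seed = 9)
  wl <- wac_matrix(nullp$profiles, de$table, planted_set)
  expect_lt(abs(mean(wl$wac, na.rm = TRUE)), 0.1)

  # graded strengths: mean wAC increases with strength (Spearman > 0.8)
  s <- seq(0.02, 1, length.out = 50)
  pan <- generate_perturbation_panel(universe, expr$truth, 50, 50, c(0, 1),
                                     1.0, seed = 10, strengths = s)
  wl2 <- wac_matrix(pan$profiles, de$table, planted_set)
  rho <- stats::cor(s, wl2$wac, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("sensitivity generator couples ln IC50 to reversal strength", {
  s <- stats::setNames(seq(0, 1, length.out = 50), sprintf("C%03d", 1:50))
  exact <- generate_sensitivity(s, alpha = 3, beta = 4, noise_sd = 0, seed = 1)
  expect_equal(stats::cor(s, exact$ln_ic50), -1)

  s100 <- stats::setNames(stats::runif(100), sprintf("C%03d", 1:100))
  flat <- generate_sensitivity(s100, alpha = 3, beta = 0, noise_sd = 1, seed = 2)
  expect_lt(abs(stats::cor(s100, flat$ln_ic50)), 0.2)

  r1 <- generate_sensitivity(s, 3, 4, 0.5, seed = 9)
  r2 <- generate_sensitivity(s, 3, 4, 0.5, seed = 9)
  expect_identical(r1, r2)

  expect_error(generate_sensitivity(s, 3, -1, 0, 1), "beta")
})

test_that("synergy screen emits all unordered pairs with symmetric signal", {
  syn <- generate_synergy_dataset(101, 16, 4, 1, 0.05, seed = 6)
  expect_equal(nrow(syn$records), 5050)  # C(101, 2)
  expect_true(all(syn$records$drug_a < syn$records$drug_b))
  expect_true(all(c("zip", "loewe", "hsa", "bliss") %in% names(syn$records)))

  # the latent signal is symmetric: recompute g with roles swapped
  fp <- syn$fingerprints
  cb <- syn$truth$causal_bits
  a <- fp[syn$records$drug_b, cb, drop = FALSE]  # deliberately swapped
  b <- fp[syn$records$drug_a, cb, drop = FALSE]
  g_swapped <- 0.7 * rowMeans((a + b) / 2) + 0.3 * rowMeans(a != b)
  expect_equal(unname(g_swapped), unname(syn$truth$g), tolerance = 1e-12)

  again <- generate_synergy_dataset(101, 16, 4, 1, 0.05, seed = 6)
  expect_identical(syn$records, again$records)

  expect_error(generate_synergy_dataset(10, 8, 9, 1, 0.1, 1), "causal")
})
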