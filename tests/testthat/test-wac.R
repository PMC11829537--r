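de_fixture <- data.frame(
  gene = c("g1", "g2", "g3", "g4", "g5"),
  log2fc = c(1.2, 0.4, -2.0, -1.0, 2.5),
  padj = c(0.001, 0.001, 0.02, 0.005, 0.0001),
  stringsAsFactors = FALSE
)

test_that("disease labelling applies both thresholds and signs", {
  lab <- label_disease(de_fixture, c("g1", "g2", "g3", "g4", "g5"))
  # g1 passes (+), g2 fails the lfc cut, g3 fails alpha, g4 (-), g5 (+)
  expect_identical(lab$gene, c("g1", "g4", "g5"))
  expect_identical(lab$label, c("+", "-", "+"))
  expect_warning(label_disease(de_fixture, c("g1", "unknown")), "not covered")
  none <- label_disease(de_fixture, "g2")
  expect_equal(nrow(none), 0)
})

test_that("treatment labelling flips the sign and marks residuals 0", {
  prof <- c(g1 = -1.0, g2 = 0.3, g3 = 2.0)
  expect_identical(label_treatment(prof, c("g1", "g2", "g3")),
                   c("+", "0", "-"))
  expect_warning(lab <- label_treatment(prof, c("g1", "g9")), "missing")
  expect_identical(lab, c("+", "0"))
  # with significance available both thresholds apply
  profdf <- data.frame(gene = c("g1", "g3"), effect = c(-1, 2),
                       padj = c(0.001, 0.5))
  expect_identical(label_treatment(profdf, c("g1", "g3")), c("+", "0"))
})

test_that("betweenness weights are affine with neutral fallback", {
  bmap <- c(g1 = 0, g2 = 0.5, g3 = 1)
  expect_equal(unname(gene_weights(bmap, c("g1", "g2", "g3"))),
               c(1, 1.5, 2))
  expect_equal(unname(gene_weights(bmap, c("x", "y"))), c(1, 1))
})

test_that("wAC reproduces the hand-computed worked example", {
  r <- wac(c("+", "+", "-", "-"), c("+", "0", "-", "+"))
  expect_equal(r$pa, 0.5)
  expect_equal(r$pe, 0.296875)
  expect_equal(r$wac, (0.5 - 0.296875) / (1 - 0.296875), tolerance = 1e-9)
})

test_that("wAC attains 1 exactly at perfect agreement and is negative at none", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    a <- sample(c("+", "-"), n, replace = TRUE)
    w <- stats::runif(n, 0.5, 3)
    r <- wac(a, a, w)
    expect_equal(r$wac, 1)
    expect_equal(r$pa, 1)
  }
  neg <- wac(c("+", "-"), c("0", "0"))
  expect_equal(neg$pa, 0)
  expect_lt(neg$wac, 0)
})

test_that("constant betweenness reduces wAC to the unweighted AC1", {
  a <- c("+", "+", "-", "+", "-")
  b <- c("+", "0", "-", "-", "-")
  const_w <- rep(1.7, 5)
  expect_equal(wac(a, b, const_w)$wac, wac(a, b)$wac, tolerance = 1e-12)
})

test_that("wAC matches the brute-force oracle on random labelled sets", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    a <- sample(c("+", "-"), n, replace = TRUE)
    b <- sample(c("+", "-", "0"), n, replace = TRUE)
    w <- stats::runif(n, 0.2, 4)
    r <- wac(a, b, w)
    if (is.na(r$wac)) next
    o <- ac1_oracle(a, b, w)
    expect_equal(r$pa, o$pa, tolerance = 1e-12)
    expect_equal(r$pe, o$pe, tolerance = 1e-12)
    expect_equal(r$wac_raw, o$ac1, tolerance = 1e-12)
    expect_lte(r$wac, 1)
    # permutation invariance
    perm <- sample(n)
    expect_equal(wac(a[perm], b[perm], w[perm])$wac, r$wac, tolerance = 1e-12)
  }
})

test_that("binary category space is available and differs from ternary", {
  a <- c("+", "+", "-", "-")
  b <- c("+", "0", "-", "+")
  r3 <- wac(a, b, category_space = "ternary")
  r2 <- wac(a, b, category_space = "binary")
  expect_false(isTRUE(all.equal(r2$pe, r3$pe)))
  expect_equal(r2$pa, r3$pa)
})

test_that("degenerate labelling yields missing results with a reason", {
  too_few <- wac("+", "+")
  expect_true(is.na(too_few$wac))
  expect_match(too_few$reason, "fewer than 2")
})

test_that("the wAC matrix separates reversers from noise compounds", {
  universe <- sprintf("G%04d", 1:150)
  wins <- 0
  for (rep in 1:100) {
    expr <- generate_expression_study(universe, 5, 5, 0.3, 3, 0.2,
                                      seed = 100 + rep)
    pan <- generate_perturbation_panel(universe, expr$truth, 2, 1,
                                       c(0.8, 0.8), 1.0, seed = 200 + rep)
    de_tab <- data.frame(gene = expr$truth$gene,
                         log2fc = expr$truth$sign * expr$truth$lfc,
                         padj = 0.0001)
    wl <- wac_matrix(pan$profiles, de_tab,
                     list(S = expr$truth$gene[1:20]))
    wm <- wac_to_matrix(wl)
    if (wm[pan$positives, "S"] > wm[setdiff(rownames(wm), pan$positives), "S"]) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 95)
})

test_that("wAC matrix records missing cells and agrees with the scalar path", {
  universe <- sprintf("G%04d", 1:100)
  expr <- generate_expression_study(universe, 5, 5, 0.3, 3, 0.2, seed = 31)
  pan <- generate_perturbation_panel(universe, expr$truth, 4, 2, c(0.5, 1),
                                     0.8, seed = 32)
  de <- call_degs(expr$counts, expr$groups)
  sets <- list(S1 = expr$truth$gene[1:15],
               EMPTY = setdiff(universe, de$table$gene[
                 de$table$padj < 0.01 & abs(de$table$log2fc) > 0.5])[1:10])
  btw <- stats::setNames(stats::runif(100), universe)
  wl <- wac_matrix(pan$profiles, de$table, sets, btw)
  expect_true(all(is.na(wl$wac[wl$set_id == "EMPTY"])))

  # vectorised matrix path equals the scalar wac() on each cell
  lab <- label_disease(de$table, sets$S1)
  w <- gene_weights(btw, lab$gene)
  for (cmp in colnames(pan$profiles)) {
    tl <- suppressWarnings(label_treatment(pan$profiles[, cmp], lab$gene))
    ref <- wac(lab$label, tl, w)
    got <- wl[wl$compound == cmp & wl$set_id == "S1", ]
    expect_equal(got$wac, ref$wac, tolerance = 1e-12)
    expect_equal(got$pa, ref$pa, tolerance = 1e-12)
  }

  # deterministic given fixed inputs
  expect_identical(wl, wac_matrix(pan$profiles, de$table, sets, btw))
})
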