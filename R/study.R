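#' Simulate a complete planted discovery study
#'
#' Composes the individual generators into one coherent synthetic study
#' with ground truth at every stage:
#'
#' * a scale-free interactome with hub-biased disease targets;
#' * planted DEGs co-located with the target neighbourhood (targets plus
#'   direct neighbours), so that planted gene-set modules drawn from that
#'   neighbourhood are simultaneously enriched for disease genes and
#'   proximal to targets, while decoy sets are neither;
#' * a reference compound panel whose positives (disease drugs) reverse
#'   the planted DEGs with graded strengths, plus two drug-sensitivity
#'   panels anti-correlated with reversal strength;
#' * a candidate panel containing a planted complementary pair: each
#'   member reverses the DEGs of half of the planted modules at full
#'   strength and the other half weakly (`secondary_strength`), so only
#'   the pair jointly covers every module.
#'
#' The defaults define the study conditions used throughout the package's
#' validation; see the methods vignette for the rationale.
#'
#' @param seed Integer master seed (sub-generators use fixed offsets).
#' @param n_nodes,attach_edges,n_targets Interactome parameters.
#' @param n_case,n_control,lfc_effect,dispersion Expression-study
#'   parameters.
#' @param n_sets,size_range,n_planted,n_redundant_pairs Gene-set
#'   collection parameters.
#' @param n_ref_compounds,n_positive,pos_strength,ref_noise Reference
#'   panel parameters (positive strengths uniform on `pos_strength`).
#' @param sens_alpha,sens_beta,sens_noise Sensitivity-panel parameters.
#' @param n_cand,cand_noise,secondary_strength Candidate panel
#'   parameters; the first two candidates are the planted pair.
#' @return List with `network`, `targets`, `universe`, `expression`,
#'   `gene_sets`, `ref_panel`, `sensitivity` (two panels), `cand_panel`,
#'   and `truth` (planted DEGs, modules, pair, strengths).
#' @export
simulate_study <- function(seed,
                           n_nodes = 300, attach_edges = 3, n_targets = 25,
                           n_case = 20, n_control = 20, lfc_effect = 3,
                           dispersion = 0.2,
                           n_sets = 40, size_range = c(25, 40),
                           n_planted = 4, n_redundant_pairs = 4,
                           n_ref_compounds = 60, n_positive = 12,
                           pos_strength = c(0.2, 0.8), ref_noise = 1.0,
                           sens_alpha = 3, sens_beta = 4, sens_noise = 0.5,
                           n_cand = 20, cand_noise = 1.0,
                           secondary_strength = 0.35) {
  net <- generate_network(n_nodes, attach_edges, n_targets, seed)
  universe <- igraph::V(net$network)$name
  gs <- generate_genesets(
    universe, n_sets, size_range, n_planted, n_redundant_pairs,
    net$targets, seed = seed + 3L, network = net$network,
    planted_bias = 0.85
  )
  # the disease dysregulates exactly its planted modules plus scattered
  # background genes (up to ~1/3 of the genome)
  module_genes <- unique(unlist(gs$gene_sets[gs$truth$planted_module_ids]))
  set.seed(seed + 1L)
  n_extra <- max(0L, round(0.33 * length(universe)) - length(module_genes))
  deg_ids <- c(module_genes,
               sample(setdiff(universe, module_genes), n_extra))
  expr <- generate_expression_study(
    universe, n_case, n_control, deg_fraction = 0.3,
    lfc_effect = lfc_effect, dispersion = dispersion,
    seed = seed + 2L, deg_ids = deg_ids
  )
  ref <- generate_perturbation_panel(
    universe, expr$truth, n_ref_compounds, n_positive,
    strength_range = pos_strength, noise_sd = ref_noise,
    seed = seed + 4L, prefix = "R"
  )
  sens <- list(
    panel1 = generate_sensitivity(ref$strengths, sens_alpha, sens_beta,
                                  sens_noise, seed = seed + 5L),
    panel2 = generate_sensitivity(ref$strengths, sens_alpha, sens_beta,
                                  sens_noise, seed = seed + 6L)
  )
  # candidate panel: first two compounds are the planted complementary pair
  planted_ids <- gs$truth$planted_module_ids
  half_a <- planted_ids[seq_len(ceiling(length(planted_ids) / 2))]
  half_b <- setdiff(planted_ids, half_a)
  genes_a <- unique(unlist(gs$gene_sets[half_a]))
  genes_b <- unique(unlist(gs$gene_sets[half_b]))
  cand <- generate_perturbation_panel(
    universe, expr$truth, n_cand, n_positive = 2,
    strength_range = c(1, 1), noise_sd = cand_noise,
    seed = seed + 7L, strengths = c(1, 1),
    reversal_genes = list(genes_a, genes_b), prefix = "T"
  )
  # weak secondary reversal of the complementary half
  add_secondary <- function(prof, col, genes, truth) {
    g <- intersect(genes, truth$gene)
    rows <- match(g, truth$gene)
    prof[g, col] <- prof[g, col] -
      truth$sign[rows] * truth$lfc[rows] * secondary_strength
    prof
  }
  cand$profiles <- add_secondary(cand$profiles, 1L, genes_b, expr$truth)
  cand$profiles <- add_secondary(cand$profiles, 2L, genes_a, expr$truth)

  list(
    network = net$network, targets = net$targets, universe = universe,
    expression = expr, gene_sets = gs$gene_sets,
    ref_panel = ref, sensitivity = sens, cand_panel = cand,
    truth = list(
      planted_deg_ids = expr$truth$gene,
      planted_module_ids = planted_ids,
      redundant_pairs = gs$truth$redundant_pairs,
      reverser_strengths = ref$strengths,
      planted_pair = colnames(cand$profiles)[1:2],
      pair_halves = list(a = half_a, b = half_b),
      seed = seed
    )
  )
}
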