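#' Synthetic study generators with planted ground truth
#'
#' Every downstream stage of the workflow (differential expression,
#' over-representation, network proximity, wAC reversal scoring, PS/TCS
#' combination scoring and fingerprint-based synergy regression) can be
#' exercised on data generated here, where the "right answer" is known by
#' construction.  All generators are pure functions of their parameters and
#' seed: rerunning with the same arguments reproduces the output bitwise.
#'
#' @name synthetic-data
NULL

#' Generate a scale-free interactome with designated disease targets
#'
#' Builds an undirected simple graph by preferential attachment
#' (Barabasi-Albert): `attach_edges` initial nodes, after which each new
#' node attaches `attach_edges` edges to distinct existing nodes with
#' probability proportional to degree.  The resulting graph is connected
#' and has `(n_nodes - attach_edges) * attach_edges` edges.  Disease
#' targets are sampled with probability proportional to degree, emulating
#' the hub bias of curated drug-target sets.
#'
#' @param n_nodes Number of genes (nodes); must exceed `attach_edges`.
#' @param attach_edges Edges attached per incoming node (the BA `m`).
#' @param n_targets Number of target genes to designate (`< n_nodes`).
#' @param seed Integer seed.
#' @return A list with `network` (an [igraph][igraph::graph] object whose
#'   vertex names are gene identifiers) and `targets` (character vector).
#' @export
generate_network <- function(n_nodes, attach_edges, n_targets, seed) {
  if (n_nodes < attach_edges + 1L) {
    stop("n_nodes must be at least attach_edges + 1")
  }
  if (n_targets >= n_nodes || n_targets < 1L) {
    stop("n_targets must be positive and smaller than n_nodes")
  }
  set.seed(seed)
  m <- as.integer(attach_edges)
  n <- as.integer(n_nodes)
  repeated <- integer(0)
  from <- integer(0)
  to <- integer(0)
  for (v in seq.int(m + 1L, n)) {
    if (v == m + 1L) {
      tg <- seq_len(m)
    } else {
      tg <- integer(0)
      while (length(tg) < m) {
        cand <- repeated[sample.int(length(repeated), 1L)]
        if (!cand %in% tg) tg <- c(tg, cand)
      }
    }
    from <- c(from, rep.int(v, m))
    to <- c(to, tg)
    repeated <- c(repeated, tg, rep.int(v, m))
  }
  ids <- sprintf("G%04d", seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(ids[from], ids[to]), directed = FALSE)
  deg <- igraph::degree(g)
  targets <- sample(igraph::V(g)$name, n_targets, prob = deg / sum(deg))
  list(network = g, targets = sort(targets))
}

#' Generate a gene-set collection with planted disease modules and
#' deliberate near-duplicates
#'
#' Planted module sets are drawn preferentially from the neighbourhood of
#' the target nodes.  When a network is supplied the targets are
#' partitioned into per-module anchor groups and each planted set is
#' built around its own anchors plus their direct neighbours, so planted
#' modules are individually proximal to targets without collapsing into
#' near-duplicates of each other; without a network the pool is the
#' target list itself.  Decoy sets are uniform draws from the universe.
#' Each redundant pair is built by copying a base set and resampling 30%
#' of its members, guaranteeing an overlap coefficient of about 0.7
#' (> 0.5) by construction.
#'
#' @param universe Character vector of gene identifiers.
#' @param n_sets Total number of gene sets to emit.
#' @param size_range Length-2 integer vector (min, max) of set sizes;
#'   must lie within `[6, 499]`.
#' @param n_planted Number of planted disease-module sets (`<= n_sets`).
#' @param n_redundant_pairs Number of redundant near-duplicate pairs; the
#'   pair members count towards `n_sets`.
#' @param targets Character vector of target gene identifiers.
#' @param seed Integer seed.
#' @param network Optional igraph network used to extend the planted pool
#'   to target neighbourhoods.
#' @param planted_bias Fraction of each planted set drawn from the target
#'   neighbourhood pool (default 0.75).
#' @return A list with `gene_sets` (named list of character vectors) and
#'   `truth` (planted ids, redundant pair table).
#' @export
generate_genesets <- function(universe, n_sets, size_range, n_planted,
                              n_redundant_pairs, targets, seed,
                              network = NULL, planted_bias = 0.75) {
  size_range <- as.integer(size_range)
  if (size_range[1] < 6L || size_range[2] > 499L || size_range[1] > size_range[2]) {
    stop("size_range must lie within [6, 499]")
  }
  if (n_planted > n_sets) stop("n_planted must not exceed n_sets")
  if (length(universe) < size_range[2]) {
    stop("universe smaller than the maximum set size")
  }
  if (n_planted + 2L * n_redundant_pairs > n_sets) {
    stop("n_planted + 2 * n_redundant_pairs must not exceed n_sets")
  }
  set.seed(seed)
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_sets, replace = TRUE)
  ids <- sprintf("SET%03d", seq_len(n_sets))
  sets <- vector("list", n_sets)
  names(sets) <- ids
  planted_ids <- ids[seq_len(n_planted)]
  if (n_planted > 0L) {
    if (!is.null(network)) {
      tg <- intersect(targets, igraph::V(network)$name)
      anchors <- split(sample(tg), rep_len(seq_len(n_planted), length(tg)))
    } else {
      anchors <- split(sample(intersect(targets, universe)),
                       rep_len(seq_len(n_planted),
                               length(intersect(targets, universe))))
    }
    for (i in seq_len(n_planted)) {
      s <- sizes[i]
      core <- intersect(anchors[[i]], universe)
      pool_i <- if (!is.null(network)) {
        setdiff(intersect(unique(unlist(lapply(
          igraph::adjacent_vertices(network, anchors[[i]]),
          function(v) v$name
        ))), universe), core)
      } else {
        character(0)
      }
      k <- min(round(planted_bias * s), length(core) + length(pool_i))
      if (k > length(core)) {
        core <- c(core, sample(pool_i, k - length(core)))
      } else {
        core <- sample(core, k)
      }
      rest <- sample(setdiff(universe, core), s - length(core))
      sets[[i]] <- sample(c(core, rest))
    }
  }
  for (i in seq.int(n_planted + 1L, n_sets)) {
    sets[[i]] <- sample(universe, sizes[i])
  }
  # overwrite the tail with redundant pairs: partner = base with 30% resampled
  pair_tab <- NULL
  if (n_redundant_pairs > 0L) {
    tail_idx <- seq.int(n_sets - 2L * n_redundant_pairs + 1L, n_sets)
    for (p in seq_len(n_redundant_pairs)) {
      i_base <- tail_idx[2L * p - 1L]
      i_part <- tail_idx[2L * p]
      base <- sets[[i_base]]
      k <- max(1L, floor(0.3 * length(base)))
      keep <- sample(base, length(base) - k)
      fresh <- sample(setdiff(universe, base), k)
      sets[[i_part]] <- sample(c(keep, fresh))
      pair_tab <- rbind(pair_tab, data.frame(
        set_a = ids[i_base], set_b = ids[i_part],
        stringsAsFactors = FALSE
      ))
    }
  }
  list(
    gene_sets = sets,
    truth = list(
      planted_module_ids = planted_ids,
      redundant_pairs = pair_tab,
      seed = seed
    )
  )
}

#' Generate a two-group negative-binomial expression study with planted DEGs
#'
#' Counts are drawn from a negative binomial with gene-specific baseline
#' means (log2 means uniform on \[3, 9\]) and common dispersion.  Planted
#' DEGs have their case-group log2 mean shifted by `+/- lfc_effect` with
#' randomised sign.
#'
#' @param universe Character vector of gene identifiers.
#' @param n_case,n_control Samples per group (each `>= 3`).
#' @param deg_fraction Fraction of genes planted as DEGs (`0 <=` and `< 1`);
#'   0 gives a pure null study.
#' @param lfc_effect Planted absolute log2 fold change.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param seed Integer seed.
#' @param deg_ids Optional explicit planted DEG identifiers (overrides
#'   `deg_fraction` sampling; must be a subset of `universe`).
#' @return A list with `counts` (genes x samples integer matrix), `groups`
#'   (character vector, "case"/"control"), and `truth`
#'   (data.frame gene / sign / lfc of planted DEGs).
#' @export
generate_expression_study <- function(universe, n_case, n_control,
                                      deg_fraction, lfc_effect, dispersion,
                                      seed, deg_ids = NULL) {
  if (n_case < 3L || n_control < 3L) stop("each group needs >= 3 samples")
  if (deg_fraction < 0 || deg_fraction >= 1) stop("deg_fraction must be in [0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  set.seed(seed)
  G <- length(universe)
  base_log2 <- stats::runif(G, 3, 9)
  if (is.null(deg_ids)) {
    n_deg <- round(deg_fraction * G)
    deg_ids <- if (n_deg > 0L) sample(universe, n_deg) else character(0)
  } else {
    stopifnot(all(deg_ids %in% universe))
  }
  sign_vec <- if (length(deg_ids)) sample(c(-1, 1), length(deg_ids), replace = TRUE) else numeric(0)
  mu_control <- 2^base_log2
  mu_case <- mu_control
  idx <- match(deg_ids, universe)
  mu_case[idx] <- 2^(base_log2[idx] + sign_vec * lfc_effect)
  size <- 1 / dispersion
  n_s <- n_case + n_control
  counts <- matrix(0L, nrow = G, ncol = n_s,
                   dimnames = list(universe, sprintf("S%03d", seq_len(n_s))))
  for (j in seq_len(n_case)) {
    counts[, j] <- stats::rnbinom(G, size = size, mu = mu_case)
  }
  for (j in seq.int(n_case + 1L, n_s)) {
    counts[, j] <- stats::rnbinom(G, size = size, mu = mu_control)
  }
  groups <- c(rep("case", n_case), rep("control", n_control))
  truth <- data.frame(
    gene = deg_ids,
    sign = sign_vec,
    lfc = rep(lfc_effect, length(deg_ids)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, groups = groups, truth = truth, seed = seed)
}

#' Generate a compound perturbation panel with planted reversers
#'
#' Each profile column holds continuous treatment effect values (a
#' compendium-style differential signature).  Positive ("reverser") compounds
#' flip the sign of every planted DEG's disease effect, scaled by a
#' compound-specific strength in `strength_range`; negative compounds are
#' pure noise.  The first `n_positive` compound ids are the positives.
#'
#' @param universe Character vector of gene identifiers (profile rows).
#' @param truth_degs Data frame with columns `gene`, `sign`, `lfc` (the
#'   `truth` of [generate_expression_study()]); must be non-empty.
#' @param n_compounds Total number of compounds.
#' @param n_positive Number of planted reversers (`<= n_compounds`).
#' @param strength_range Length-2 numeric (lo, hi) in `[0, 1]` from which
#'   reverser strengths are drawn uniformly.
#' @param noise_sd Gaussian noise standard deviation added to every entry.
#' @param seed Integer seed.
#' @param strengths Optional explicit strengths for the positives
#'   (length `n_positive`), overriding the uniform draw.
#' @param reversal_genes Optional list (length `n_positive`) of gene-id
#'   vectors each positive reverses; default: all planted DEGs.
#' @param prefix Compound id prefix (default `"C"`), so independent panels
#'   can carry disjoint namespaces.
#' @return A list with `profiles` (genes x compounds numeric matrix),
#'   `positives` (character), and `strengths` (named numeric over all
#'   compounds; 0 for negatives).
#' @export
generate_perturbation_panel <- function(universe, truth_degs, n_compounds,
                                        n_positive, strength_range, noise_sd,
                                        seed, strengths = NULL,
                                        reversal_genes = NULL, prefix = "C") {
  if (is.null(truth_degs) || nrow(truth_degs) == 0L) {
    stop("truth_degs must contain at least one planted DEG")
  }
  if (n_positive > n_compounds) stop("n_positive must not exceed n_compounds")
  set.seed(seed)
  ids <- sprintf("%s%03d", prefix, seq_len(n_compounds))
  prof <- matrix(stats::rnorm(length(universe) * n_compounds, sd = noise_sd),
                 nrow = length(universe),
                 dimnames = list(universe, ids))
  s_all <- stats::setNames(rep(0, n_compounds), ids)
  if (n_positive > 0L) {
    s_pos <- if (is.null(strengths)) {
      stats::runif(n_positive, strength_range[1], strength_range[2])
    } else {
      stopifnot(length(strengths) == n_positive)
      strengths
    }
    s_all[seq_len(n_positive)] <- s_pos
    for (i in seq_len(n_positive)) {
      genes <- if (is.null(reversal_genes)) truth_degs$gene else reversal_genes[[i]]
      rows <- match(intersect(genes, truth_degs$gene), truth_degs$gene)
      g <- truth_degs$gene[rows]
      prof[g, i] <- prof[g, i] - truth_degs$sign[rows] * truth_degs$lfc[rows] * s_pos[i]
    }
  }
  list(profiles = prof, positives = ids[seq_len(n_positive)],
       strengths = s_all, seed = seed)
}

#' Generate ln(IC50) drug-sensitivity values anti-correlated with reversal
#' strength
#'
#' `ln_ic50(c) = alpha - beta * strength(c) + N(0, noise_sd)`: stronger
#' reversers are more sensitive (lower ln IC50).
#'
#' @param strengths Named numeric vector of reversal strengths per compound.
#' @param alpha Intercept (baseline ln IC50).
#' @param beta Positive slope coupling strength to sensitivity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with columns `compound`, `ln_ic50`.
#' @export
generate_sensitivity <- function(strengths, alpha, beta, noise_sd, seed) {
  if (beta < 0) stop("beta must be non-negative")
  set.seed(seed)
  data.frame(
    compound = names(strengths),
    ln_ic50 = alpha - beta * as.numeric(strengths) +
      stats::rnorm(length(strengths), sd = noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Generate a pairwise synergy screen driven by planted fingerprint bits
#'
#' Random binary fingerprints are assigned to each drug; for every
#' unordered pair the latent synergy signal is a symmetric function of the
#' causal bits, `g = 0.7 * additive + 0.3 * complementarity`, where
#' `additive` is the mean of `(a_i + b_i)/2` and `complementarity` the mean
#' of `xor(a_i, b_i)` over causal bits.  Four synergy fields (zip, loewe,
#' hsa, bliss) are correlated noisy transforms of the same signal.
#'
#' @param n_drugs Number of drugs.
#' @param fp_length Fingerprint length in bits.
#' @param n_causal_bits Number of causal bits (`<= fp_length`).
#' @param interaction_effect Scale of the planted signal; 0 gives pure
#'   noise targets.
#' @param noise_sd Gaussian noise standard deviation on each synergy field.
#' @param seed Integer seed.
#' @param base Baseline synergy level (default 0).
#' @return A list with `records` (data.frame drug_a, drug_b, cell, zip,
#'   loewe, hsa, bliss), `fingerprints` (drugs x bits 0/1 matrix), and
#'   `truth` (causal bit indices and latent `g` per pair).
#' @export
generate_synergy_dataset <- function(n_drugs, fp_length, n_causal_bits,
                                     interaction_effect, noise_sd, seed,
                                     base = 0) {
  if (n_causal_bits > fp_length) stop("n_causal_bits must not exceed fp_length")
  set.seed(seed)
  ids <- sprintf("D%03d", seq_len(n_drugs))
  fp <- matrix(stats::rbinom(n_drugs * fp_length, 1L, 0.3),
               nrow = n_drugs,
               dimnames = list(ids, sprintf("bit%03d", seq_len(fp_length))))
  causal <- sort(sample.int(fp_length, n_causal_bits))
  pairs <- t(utils::combn(ids, 2L))
  a <- fp[pairs[, 1], causal, drop = FALSE]
  b <- fp[pairs[, 2], causal, drop = FALSE]
  additive <- rowMeans((a + b) / 2)
  comp <- rowMeans(a != b)
  g <- 0.7 * additive + 0.3 * comp
  n_p <- nrow(pairs)
  mk <- function(scale, extra_noise) {
    base + scale * interaction_effect * g + stats::rnorm(n_p, sd = noise_sd * extra_noise)
  }
  records <- data.frame(
    drug_a = pairs[, 1], drug_b = pairs[, 2], cell = "SYN-CELL",
    zip = mk(1, 1), loewe = mk(0.9, 1.1), hsa = mk(0.8, 1.2),
    bliss = mk(1.1, 1.1),
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    fingerprints = fp,
    truth = list(causal_bits = causal, g = g, seed = seed,
                 interaction_effect = interaction_effect, noise_sd = noise_sd)
  )
}
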