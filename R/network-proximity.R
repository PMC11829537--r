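#' Normalized betweenness centrality
#'
#' Shortest-path betweenness of every node, normalized by
#' `(n-1)(n-2)/2` (undirected), so values lie in `[0, 1]`.
#'
#' @param network An igraph graph with named vertices.
#' @return Named numeric vector of normalized betweenness values.
#' @export
node_betweenness <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty graph")
  igraph::betweenness(network, directed = FALSE, normalized = TRUE)
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) * W %*% p + r * p0` with `W` the column-degree-
#' normalized adjacency matrix and `p0` uniform over the seed nodes mapped
#' into the network, until the L1 change drops below `tol`.  Probability
#' mass reaching a degree-0 node is teleported back to `p0`, so the
#' stationary vector always sums to 1.
#'
#' @param network An igraph graph with named vertices.
#' @param seed_nodes Character vector of seed gene ids; at least one must
#'   map into the network.
#' @param restart Restart probability `r` in (0, 1) (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Maximum iterations (default 1000).
#' @return Named numeric vector of stationary visiting probabilities.
#' @export
rwr <- function(network, seed_nodes, restart = 0.5, tol = 1e-10,
                max_iter = 1000) {
  if (restart <= 0 || restart >= 1) stop("restart must be in (0, 1)")
  nodes <- igraph::V(network)$name
  seeds <- intersect(seed_nodes, nodes)
  if (length(seeds) == 0L) stop("no seed node maps into the network")
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::colSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = inv_deg)
  p0 <- stats::setNames(rep(0, length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  dangling <- deg == 0
  p <- p0
  for (it in seq_len(max_iter)) {
    spread <- as.numeric(W %*% p)
    lost <- sum(p[dangling])
    p_new <- (1 - restart) * (spread + lost * p0) + restart * p0
    if (sum(abs(p_new - p)) < tol) {
      return(stats::setNames(p_new, nodes))
    }
    p <- p_new
  }
  stop(sprintf("random walk did not converge within %d iterations", max_iter))
}

#' Mean stationary probability of a gene set
#'
#' Arithmetic mean of RWR stationary probabilities over the set genes
#' present in the network; the mapped fraction is reported as coverage.
#'
#' @param stationary Named stationary probability vector from [rwr()].
#' @param gene_set Character vector of gene ids.
#' @return List with `observed` (mean probability; `NA` with a warning
#'   when no gene maps) and `coverage`.
#' @export
geneset_proximity <- function(stationary, gene_set) {
  gene_set <- unique(gene_set)
  mapped <- intersect(gene_set, names(stationary))
  if (length(mapped) == 0L) {
    warning("no gene of the set maps into the network")
    return(list(observed = NA_real_, coverage = 0))
  }
  list(observed = mean(stationary[mapped]),
       coverage = length(mapped) / length(gene_set))
}

#' Permutation test of gene-set proximity to disease targets
#'
#' Computes RWR stationary probabilities seeded at the targets, scores
#' each gene set by the mean probability of its mapped genes, and compares
#' against a null of size-matched random gene sets.  The empirical
#' one-tailed p uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never 0; p-values
#' are BH-adjusted across sets and a set is selected iff `padj < alpha`.
#'
#' Two null schemes are available: `"genesets"` (default) redraws random
#' gene sets of matched size from the network nodes (optionally matched on
#' log2-degree bins to guard against hub bias); `"targets"` redraws random
#' size-matched pseudo-target sets and recomputes the walk, which is far
#' more expensive.
#'
#' @param network An igraph graph with named vertices.
#' @param gene_sets Named list of character vectors.
#' @param targets Character vector of target gene ids.
#' @param n_perm Number of permutations (`>= 100`, default 1000).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param restart RWR restart probability (default 0.5).
#' @param seed Optional integer seed for the permutation draws.
#' @param null `"genesets"` or `"targets"`.
#' @param degree_match Match null draws on log2-degree bins
#'   (`null = "genesets"` only).
#' @return List with `table` (set_id, observed, coverage, perm_p, padj),
#'   `selected`, and `stationary` (the RWR vector, reusable downstream).
#' @export
proximity_permutation_test <- function(network, gene_sets, targets,
                                       n_perm = 1000, alpha = 0.01,
                                       restart = 0.5, seed = NULL,
                                       null = c("genesets", "targets"),
                                       degree_match = FALSE) {
  null <- match.arg(null)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  stationary <- rwr(network, targets, restart = restart)
  nodes <- names(stationary)
  obs <- lapply(gene_sets, function(s) geneset_proximity(stationary, s))
  observed <- vapply(obs, `[[`, numeric(1), "observed")
  coverage <- vapply(obs, `[[`, numeric(1), "coverage")
  sizes <- vapply(gene_sets, function(s) {
    length(intersect(unique(s), nodes))
  }, integer(1))

  if (null == "genesets") {
    if (degree_match) {
      deg <- igraph::degree(network)
      bins <- floor(log2(deg + 1))
      by_bin <- split(nodes, bins)
      set_bins <- lapply(gene_sets, function(s) {
        bins[match(intersect(unique(s), nodes), nodes)]
      })
    }
    perm_p <- vapply(seq_along(gene_sets), function(i) {
      k <- sizes[i]
      if (k == 0L || is.na(observed[i])) return(NA_real_)
      null_means <- if (degree_match) {
        cnt <- table(set_bins[[i]])
        vapply(seq_len(n_perm), function(b) {
          draw <- unlist(lapply(names(cnt), function(bn) {
            sample(by_bin[[bn]], cnt[[bn]], replace = length(by_bin[[bn]]) < cnt[[bn]])
          }))
          mean(stationary[draw])
        }, numeric(1))
      } else {
        vapply(seq_len(n_perm), function(b) {
          mean(stationary[sample.int(length(nodes), k)])
        }, numeric(1))
      }
      (1 + sum(null_means >= observed[i])) / (1 + n_perm)
    }, numeric(1))
  } else {
    kt <- length(intersect(targets, nodes))
    null_mat <- vapply(seq_len(n_perm), function(b) {
      st <- rwr(network, sample(nodes, kt), restart = restart)
      vapply(gene_sets, function(s) {
        mapped <- intersect(unique(s), nodes)
        if (!length(mapped)) NA_real_ else mean(st[mapped])
      }, numeric(1))
    }, numeric(length(gene_sets)))
    null_mat <- matrix(null_mat, nrow = length(gene_sets))
    perm_p <- vapply(seq_along(gene_sets), function(i) {
      if (is.na(observed[i])) return(NA_real_)
      (1 + sum(null_mat[i, ] >= observed[i], na.rm = TRUE)) / (1 + n_perm)
    }, numeric(1))
  }

  tab <- data.frame(
    set_id = names(gene_sets), observed = observed, coverage = coverage,
    perm_p = perm_p, padj = stats::p.adjust(perm_p, "BH"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab,
       selected = tab$set_id[!is.na(tab$padj) & tab$padj < alpha],
       stationary = stationary)
}
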