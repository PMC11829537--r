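#' Assemble a pipeline configuration
#'
#' Inputs can be in-memory objects (matrices, data frames, igraph
#' networks, lists of gene sets) or file paths understood by
#' [read_table()] / [read_gmt()]; paths are loaded lazily when the
#' pipeline runs.  Thresholds default to the workflow's standard values.
#'
#' @param counts Count matrix or TSV path (alternative: `de_table`).
#' @param groups Group labels over count columns.
#' @param de_table Precomputed DE table (or TSV path), used verbatim.
#' @param gene_sets Named list or GMT path.
#' @param network igraph network, or `edges` data frame / TSV path.
#' @param edges Edge list alternative to `network`.
#' @param targets Character vector of target gene ids, or path to a
#'   plain-text file with one id per line.
#' @param ref_profiles Reference compound panel (genes x compounds matrix
#'   or TSV path) with known positives.
#' @param positives Character vector of positive compound ids.
#' @param sensitivity Named list of sensitivity tables (or TSV paths).
#' @param cand_profiles Candidate compound panel (matrix or TSV path).
#' @param cand_fingerprints Optional named list (per fingerprint type) of
#'   precomputed fingerprint matrices for the candidates.
#' @param ml_bundles Optional named list (per fingerprint type) of
#'   trained bundles from [train_select()].
#' @param de_alpha,de_lfc DEG thresholds (0.01, 1.0).
#' @param ora_alpha,size_min,size_max ORA thresholds (0.01, 6, 499).
#' @param overlap_max Redundancy threshold (0.5).
#' @param restart,n_perm,prox_alpha Proximity parameters (0.5, 1000, 0.01).
#' @param wac_alpha,wac_lfc,effect_cut wAC labelling thresholds
#'   (0.01, 0.5, 0.5).
#' @param sig_alpha,panel_rule Signature selection (0.01, "any").
#' @param tcs_threshold Strict TCS bound (`NULL` = number of signature
#'   sets minus one).
#' @param seed Integer seed for permutation draws.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(counts = NULL, groups = NULL, de_table = NULL,
                            gene_sets = NULL, network = NULL, edges = NULL,
                            targets = NULL, ref_profiles = NULL,
                            positives = NULL, sensitivity = NULL,
                            cand_profiles = NULL, cand_fingerprints = NULL,
                            ml_bundles = NULL,
                            de_alpha = 0.01, de_lfc = 1.0,
                            ora_alpha = 0.01, size_min = 6, size_max = 499,
                            overlap_max = 0.5, restart = 0.5,
                            n_perm = 1000, prox_alpha = 0.01,
                            wac_alpha = 0.01, wac_lfc = 0.5,
                            effect_cut = 0.5, sig_alpha = 0.01,
                            panel_rule = "any", tcs_threshold = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

.load_input <- function(x, kind) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("input file not found: %s", x))
    switch(kind,
      gmt = read_gmt(x),
      targets = readLines(x),
      read_table(x, kind)
    )
  } else {
    x
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full combination-discovery pipeline
#'
#' Executes differential expression, over-representation analysis,
#' network-proximity filtering, redundancy pruning, wAC scoring of the
#' reference panel, signature selection, grading of the candidate panel,
#' PS/TCS pair ranking, and -- when fingerprint models are configured --
#' structure-based synergy prediction for the TCS-passing pairs (ranked
#' by ensemble predicted synergy).  Each stage's table is written under
#' `outdir` together with a provenance JSON of the parameters used.
#'
#' @param config A [pipeline_config()] object.
#' @param outdir Optional output directory for stage tables and
#'   provenance.
#' @return List of per-stage results; `$ranking` holds the final
#'   candidate pair table.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, df) {
    if (!is.null(outdir) && is.data.frame(df)) {
      utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    df
  }

  gene_sets <- .load_input(config$gene_sets, "gmt")
  network <- if (!is.null(config$network)) config$network else {
    e <- .load_input(config$edges, "edges")
    igraph::graph_from_data_frame(e, directed = FALSE)
  }
  targets <- .load_input(config$targets, "targets")

  # 1. differential expression
  de <- .stage("differential_expression", {
    if (!is.null(config$de_table)) {
      call_degs(de_table = .load_input(config$de_table, "de_table"),
                alpha = config$de_alpha, lfc_cut = config$de_lfc)
    } else {
      call_degs(.load_input(config$counts, "counts"), config$groups,
                alpha = config$de_alpha, lfc_cut = config$de_lfc)
    }
  })
  emit("de_table", de$table)
  universe <- de$table$gene

  # 2. over-representation
  enr <- .stage("enrichment", {
    ora(de$degs, universe, gene_sets, alpha = config$ora_alpha,
        size_min = config$size_min, size_max = config$size_max)
  })
  emit("ora_table", enr$table)

  # 3. proximity to targets
  prox <- .stage("network_proximity", {
    proximity_permutation_test(
      network, gene_sets[enr$selected], targets,
      n_perm = config$n_perm, alpha = config$prox_alpha,
      restart = config$restart, seed = config$seed
    )
  })
  emit("proximity_table", prox$table)

  # 4. redundancy pruning (enrichment significance decides ties)
  pruned <- .stage("redundancy_pruning", {
    ids <- prox$selected
    padj <- stats::setNames(enr$table$padj, enr$table$set_id)[ids]
    prune_redundant(gene_sets[ids], padj, threshold = config$overlap_max)
  })

  # 5. wAC of the reference panel on the retained sets
  btw <- .stage("betweenness", node_betweenness(network))
  wac_ref <- .stage("wac_reference", {
    wac_matrix(.load_input(config$ref_profiles, "profiles"), de$table,
               gene_sets[pruned], btw, alpha = config$wac_alpha,
               lfc_cut = config$wac_lfc, effect_cut = config$effect_cut)
  })
  emit("wac_reference", wac_ref)
  wm_ref <- wac_to_matrix(wac_ref)

  # 6. signature selection
  sig <- .stage("signature_selection", {
    panels <- lapply(config$sensitivity, .load_input, kind = "sensitivity")
    wil <- compare_groups(wm_ref, config$positives)
    corr <- sensitivity_correlation(wm_ref, panels)
    select_signature(wil, corr, alpha = config$sig_alpha,
                     panel_rule = config$panel_rule)
  })
  emit("signature_verdicts", sig$verdicts)
  if (length(sig$selected) == 0L) {
    stop("pipeline stage 'signature_selection' failed: no signature set selected")
  }

  # 7. grading, PS/TCS ranking of the candidate panel
  scoring <- .stage("synergy_scoring", {
    qs <- reference_quantiles(wm_ref[, sig$selected, drop = FALSE],
                              config$positives)
    wac_cand <- wac_matrix(.load_input(config$cand_profiles, "profiles"),
                           de$table, gene_sets[sig$selected], btw,
                           alpha = config$wac_alpha,
                           lfc_cut = config$wac_lfc,
                           effect_cut = config$effect_cut)
    gm <- grade_matrix(wac_to_matrix(wac_cand), qs)
    list(quantiles = qs, wac_cand = wac_cand, grades = gm,
         pairs = rank_candidates(gm, tcs_threshold = config$tcs_threshold))
  })
  emit("candidate_pairs", scoring$pairs)

  # 8. structure-based synergy prediction of the passing pairs
  ranking <- scoring$pairs
  if (!is.null(config$ml_bundles) && nrow(ranking) > 0L) {
    ranking <- .stage("ml_prediction", {
      fp_of <- function(tab, ft, id) {
        if (!id %in% rownames(tab)) {
          stop(sprintf("no %s fingerprint for candidate '%s'", ft, id))
        }
        as_fingerprint(tab[id, ], id, ft)
      }
      preds <- vapply(seq_len(nrow(ranking)), function(i) {
        fa <- mapply(fp_of, config$cand_fingerprints,
                     names(config$cand_fingerprints),
                     MoreArgs = list(id = ranking$compound_a[i]),
                     SIMPLIFY = FALSE)
        fb <- mapply(fp_of, config$cand_fingerprints,
                     names(config$cand_fingerprints),
                     MoreArgs = list(id = ranking$compound_b[i]),
                     SIMPLIFY = FALSE)
        predict_pair(fa, fb, config$ml_bundles)$ensemble
      }, numeric(1))
      ranking$predicted_synergy <- preds
      ranking[order(-ranking$predicted_synergy, ranking$compound_a), ]
    })
    rownames(ranking) <- NULL
  }
  emit("final_ranking", ranking)

  if (!is.null(outdir)) {
    prov <- config[!vapply(config, is.function, logical(1))]
    keep <- c("de_alpha", "de_lfc", "ora_alpha", "size_min", "size_max",
              "overlap_max", "restart", "n_perm", "prox_alpha", "wac_alpha",
              "wac_lfc", "effect_cut", "sig_alpha", "panel_rule",
              "tcs_threshold", "seed")
    jsonlite::write_json(
      list(parameters = prov[keep],
           package_version = as.character(utils::packageVersion("synergene")),
           n_signature_sets = length(sig$selected)),
      file.path(outdir, "provenance.json"),
      auto_unbox = TRUE, null = "null", digits = NA
    )
  }

  list(de = de, enrichment = enr, proximity = prox, pruned = pruned,
       wac_reference = wac_ref, signature = sig, scoring = scoring,
       ranking = ranking)
}
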