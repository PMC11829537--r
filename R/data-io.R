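#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, fields are name,
#' description, then member genes.  Duplicate genes within a set are
#' deduplicated (first occurrence kept); a line with fewer than three
#' fields is a parse error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; set descriptions are kept in
#'   the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", bad[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT file")
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (default `"na"`).
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(gene_sets, "descriptions")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(gene_sets), descriptions, gene_sets)
  writeLines(lines, path)
  invisible(path)
}

.required_cols <- list(
  de_table = c("gene", "log2fc", "padj"),
  edges = c("from", "to"),
  sensitivity = c("compound", "ln_ic50"),
  synergy = c("drug_a", "drug_b"),
  smiles = c("compound_id", "smiles")
)

#' Read and validate a typed input table
#'
#' Readers reject rather than coerce malformed input.  `counts` and
#' `profiles` are gene x sample/compound matrices (first column = gene id);
#' `de_table`, `edges`, `sensitivity`, `synergy` and `smiles` are data
#' frames with required named columns.  `counts`/`profiles`/`de_table`/
#' `edges`/`sensitivity` are tab-separated; `synergy` and `smiles` are CSV.
#'
#' Required columns: `de_table`: gene, log2fc, padj; `edges`: from, to
#' (self-loops dropped with a warning); `sensitivity`: compound, ln_ic50;
#' `synergy`: drug_a, drug_b plus at least one of zip/loewe/hsa/bliss;
#' `smiles`: compound_id, smiles.
#'
#' @param path Path to the file.
#' @param kind One of `"counts"`, `"de_table"`, `"profiles"`, `"edges"`,
#'   `"sensitivity"`, `"synergy"`, `"smiles"`.
#' @return A matrix (`counts`, `profiles`) or data frame.
#' @export
read_table <- function(path, kind = c("counts", "de_table", "profiles",
                                      "edges", "sensitivity", "synergy",
                                      "smiles")) {
  kind <- match.arg(kind)
  sep <- if (kind %in% c("synergy", "smiles")) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"")
  req <- .required_cols[[kind]]
  if (!is.null(req) && !all(req %in% names(df))) {
    stop(sprintf("schema error for kind '%s': expected columns {%s}, found {%s}",
                 kind, paste(req, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  }
  switch(kind,
    counts = {
      mat <- .as_gene_matrix(df)
      if (anyNA(mat)) stop("counts contain missing values")
      if (any(mat < 0)) stop("counts contain negative entries")
      mat
    },
    profiles = {
      mat <- .as_gene_matrix(df)
      if (anyNA(mat)) stop("profiles contain missing values")
      mat
    },
    de_table = {
      if (!is.numeric(df$log2fc) || !is.numeric(df$padj)) {
        stop("de_table columns log2fc and padj must be numeric")
      }
      if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
        stop("de_table padj values outside [0, 1]")
      }
      if (anyDuplicated(df$gene)) stop("de_table has duplicated gene rows")
      df[, c("gene", "log2fc", "padj")]
    },
    edges = {
      df$from <- as.character(df$from); df$to <- as.character(df$to)
      loops <- df$from == df$to
      if (any(loops)) {
        warning(sprintf("dropped %d self-loop(s) from edge list", sum(loops)))
        df <- df[!loops, , drop = FALSE]
      }
      df[, c("from", "to")]
    },
    sensitivity = {
      if (!is.numeric(df$ln_ic50)) stop("sensitivity ln_ic50 must be numeric")
      df
    },
    synergy = {
      score_cols <- intersect(c("zip", "loewe", "hsa", "bliss"), names(df))
      if (!length(score_cols)) {
        stop("schema error for kind 'synergy': need at least one of zip/loewe/hsa/bliss")
      }
      for (sc in score_cols) {
        if (!is.numeric(df[[sc]])) stop(sprintf("synergy column '%s' must be numeric", sc))
      }
      df
    },
    smiles = df
  )
}

.as_gene_matrix <- function(df) {
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicated gene identifiers")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in matrix columns")
  rownames(mat) <- genes
  mat
}

#' Write a gene x column matrix as TSV (first column `gene`)
#'
#' Output files round-trip through [read_table()].
#'
#' @param mat Numeric matrix with gene-id rownames.
#' @param path Output path.
#' @export
write_gene_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select one perturbation profile per compound
#'
#' Applies the profile-selection rule used for multi-profile compounds:
#' keep the 24-hour timepoint, and among those profiles take the one with
#' the highest transcriptional activity score.  Compounds without a 24-h
#' profile are dropped (with a message).  Ties on the activity score are
#' broken deterministically towards the lexicographically smallest profile
#' id (logged).
#'
#' @param metadata Data frame with columns `profile_id`, `compound_id`,
#'   `timepoint` (hours), `activity_score`.
#' @param timepoint Required timepoint in hours (default 24).
#' @param strict If `TRUE` (default), compounds lacking the timepoint are
#'   dropped; if `FALSE`, the nearest available timepoint is used instead.
#' @return Data frame with columns `compound_id`, `profile_id`.
#' @export
select_profiles <- function(metadata, timepoint = 24, strict = TRUE) {
  req <- c("profile_id", "compound_id", "timepoint", "activity_score")
  if (!all(req %in% names(metadata)) || nrow(metadata) == 0L) {
    stop("metadata must be non-empty with columns profile_id, compound_id, timepoint, activity_score")
  }
  picks <- lapply(split(metadata, metadata$compound_id), function(rows) {
    at_tp <- rows[rows$timepoint == timepoint, , drop = FALSE]
    if (nrow(at_tp) == 0L) {
      if (strict) return(NULL)
      nearest <- rows$timepoint[which.min(abs(rows$timepoint - timepoint))]
      at_tp <- rows[rows$timepoint == nearest, , drop = FALSE]
    }
    best <- at_tp[at_tp$activity_score == max(at_tp$activity_score), , drop = FALSE]
    if (nrow(best) > 1L) {
      message(sprintf("compound %s: activity-score tie broken towards profile %s",
                      best$compound_id[1], min(best$profile_id)))
      best <- best[order(best$profile_id), , drop = FALSE]
    }
    best[1L, c("compound_id", "profile_id")]
  })
  dropped <- names(picks)[vapply(picks, is.null, logical(1))]
  if (length(dropped)) {
    message(sprintf("dropped %d compound(s) without a %g-h profile: %s",
                    length(dropped), timepoint,
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  out <- do.call(rbind, picks[!vapply(picks, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Serialise a synthetic-truth object to JSON
#'
#' @param truth List as produced by the generators.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a synthetic-truth JSON file
#'
#' @param path Path written by [write_truth()].
#' @return List.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
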