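.fp_registry <- c(MACCS = 166L, CDKSubstructure = 307L, PubChem = 881L)

#' Registered fingerprint length
#'
#' The three supported substructure-key fingerprint dialects have fixed
#' lengths: MACCS 166 bits, CDK Substructure 307 bits, PubChem 881 bits.
#'
#' @param fp_type Fingerprint type name.
#' @return Integer bit length.
#' @export
registry_length <- function(fp_type) {
  if (!fp_type %in% names(.fp_registry)) {
    stop(sprintf("unknown fingerprint type '%s' (supported: %s)",
                 fp_type, paste(names(.fp_registry), collapse = ", ")))
  }
  .fp_registry[[fp_type]]
}

#' Encode a compound structure as a binary fingerprint
#'
#' MACCS fingerprints are computed natively through the OpenBabel backend
#' (ChemmineOB); the 256-padded OpenBabel bit vector is truncated to the
#' 166 standard keys.  PubChem and CDK Substructure dialects vary by
#' toolkit, so they are served from a precomputed fingerprint table
#' (compound id x bit columns) rather than recomputed; a table can also
#' be supplied for MACCS (e.g. synthetic fingerprints in tests).  The
#' emitted length always matches [registry_length()].
#'
#' @param smiles SMILES string (ignored when a table row is used with
#'   `compound_id`).
#' @param fp_type One of `"MACCS"`, `"CDKSubstructure"`, `"PubChem"`.
#' @param table Optional precomputed fingerprint matrix (rownames =
#'   compound ids) or data frame with a `compound_id` column.
#' @param compound_id Row key into `table`.
#' @return Object of class `"fingerprint"`: list with `compound_id`,
#'   `fp_type`, `bits` (integer 0/1 vector of registry length).
#' @export
encode <- function(smiles = NULL, fp_type = "MACCS", table = NULL,
                   compound_id = NULL) {
  len <- registry_length(fp_type)
  if (!is.null(table)) {
    if (is.data.frame(table)) {
      rn <- table$compound_id
      table <- as.matrix(table[, setdiff(names(table), "compound_id")])
      rownames(table) <- rn
    }
    if (is.null(compound_id) || !compound_id %in% rownames(table)) {
      stop(sprintf("no precomputed fingerprint row for compound '%s'",
                   if (is.null(compound_id)) "<missing id>" else compound_id))
    }
    bits <- as.integer(table[compound_id, ])
    if (length(bits) != len) {
      stop(sprintf("precomputed %s fingerprint has %d bits, expected %d",
                   fp_type, length(bits), len))
    }
    return(structure(list(compound_id = compound_id, fp_type = fp_type,
                          bits = bits), class = "fingerprint"))
  }
  if (fp_type != "MACCS") {
    stop(sprintf("%s fingerprints require a precomputed table", fp_type))
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required to compute MACCS fingerprints natively")
  }
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "MACCS"
    ),
    error = function(e) {
      stop(sprintf("could not parse structure '%s'", smiles), call. = FALSE)
    }
  )
  bits <- as.integer(raw)[seq_len(len)]
  structure(list(compound_id = if (is.null(compound_id)) smiles else compound_id,
                 fp_type = fp_type, bits = bits),
            class = "fingerprint")
}

#' Construct a fingerprint object from raw bits
#'
#' For registered fingerprint types the bit length is validated against
#' [registry_length()]; unregistered types (e.g. synthetic fingerprints)
#' are accepted with any length.
#'
#' @param bits Integer 0/1 vector.
#' @param compound_id Compound identifier.
#' @param fp_type Fingerprint type name.
#' @return `"fingerprint"` object.
#' @export
as_fingerprint <- function(bits, compound_id, fp_type) {
  bits <- as.integer(bits)
  if (fp_type %in% names(.fp_registry) &&
      length(bits) != .fp_registry[[fp_type]]) {
    stop(sprintf("%s fingerprint has %d bits, expected %d",
                 fp_type, length(bits), .fp_registry[[fp_type]]))
  }
  structure(list(compound_id = compound_id, fp_type = fp_type, bits = bits),
            class = "fingerprint")
}

#' Featurize an unordered compound pair in both concatenation orders
#'
#' Each pair yields two feature rows -- `bits_a || bits_b` (order AB) and
#' `bits_b || bits_a` (order BA) -- tagged with the same order-free pair
#' id `A|B` with `A < B` lexicographically.
#'
#' @param fp_a,fp_b `"fingerprint"` objects of the same type.
#' @return List with `pair_id`, `fp_type`, `AB`, `BA` (integer vectors of
#'   twice the registry length).
#' @export
featurize_pair <- function(fp_a, fp_b) {
  if (fp_a$fp_type != fp_b$fp_type) {
    stop("fingerprint types differ between the pair members")
  }
  ids <- sort(c(fp_a$compound_id, fp_b$compound_id))
  list(pair_id = paste(ids, collapse = "|"),
       fp_type = fp_a$fp_type,
       AB = c(fp_a$bits, fp_b$bits),
       BA = c(fp_b$bits, fp_a$bits))
}

#' Order-free pair identifier
#'
#' @param a,b Compound ids.
#' @return Character `min|max` key.
#' @export
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
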