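#' Construct a gene expression signature
#'
#' A gene expression signature (GES) is the pair of up- and down-regulated
#' gene sets characterizing a perturbation (drug treatment) or condition
#' (disease). Signatures are stored one per row in a tibble with list-columns
#' `up_genes` / `down_genes`; a collection of such rows is validated with
#' [validate_signatures()].
#'
#' @param signature_id Unique identifier, e.g. `"drug:2772"` or `"dz:297"`.
#' @param up_genes,down_genes Character vectors of gene symbols; normalized
#'   with [normalize_gene_symbols()].
#' @param entity_kind `"drug"` or `"disease"`. Default inferred from the
#'   `signature_id` prefix (`"drug:"` / `"dz:"`).
#' @param entity_name Drug or disease name; defaults to `signature_id`.
#' @param series_id Source series accession (e.g. a GEO `GSE` id) used for
#'   dual-label resolution.
#' @param organism Source organism label, default `"human"`.
#' @return One-row tibble.
#' @examples
#' ges_signature("drug:1", up_genes = c("MX1"), down_genes = c("FTL"))
#' @export
ges_signature <- function(signature_id, up_genes = character(),
                          down_genes = character(),
                          entity_kind = NULL, entity_name = signature_id,
                          series_id = NA_character_, organism = "human") {
  if (is.null(entity_kind)) {
    entity_kind <- if (startsWith(signature_id, "dz:")) "disease" else "drug"
  }
  entity_kind <- match.arg(entity_kind, c("drug", "disease"))
  tibble(
    signature_id = as.character(signature_id),
    series_id = as.character(series_id),
    entity_kind = entity_kind,
    entity_name = normalize_entity_name(entity_name),
    organism = as.character(organism),
    up_genes = list(normalize_gene_symbols(up_genes)),
    down_genes = list(normalize_gene_symbols(down_genes))
  )
}

#' Validate a signature collection
#'
#' Enforces the signature invariants: unique ids, non-empty gene content,
#' and disjoint up/down sets. A gene listed in both directions of one
#' signature carries a contradictory direction and is removed from both sets
#' with a warning (keeping it would inflate both the same- and cross-terms
#' of the signed Jaccard index).
#'
#' @param signatures Tibble of signatures ([ges_signature()] rows).
#' @return The validated tibble.
#' @export
validate_signatures <- function(signatures) {
  stopifnot(is.data.frame(signatures))
  required <- c("signature_id", "series_id", "entity_kind", "entity_name",
                "organism", "up_genes", "down_genes")
  missing <- setdiff(required, names(signatures))
  if (length(missing)) {
    abort(paste0("signature table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  dup <- unique(signatures$signature_id[duplicated(signatures$signature_id)])
  if (length(dup)) {
    abort(paste0("duplicated signature ids: ", paste(dup, collapse = ", ")))
  }
  up <- lapply(signatures$up_genes, normalize_gene_symbols)
  dn <- lapply(signatures$down_genes, normalize_gene_symbols)
  both <- mapply(function(u, d) intersect(u, d), up, dn, SIMPLIFY = FALSE)
  n_both <- lengths(both)
  if (any(n_both > 0L)) {
    ids <- signatures$signature_id[n_both > 0L]
    warn(paste0("genes listed both up and down removed from: ",
                paste(ids, collapse = ", ")))
    up <- mapply(setdiff, up, both, SIMPLIFY = FALSE)
    dn <- mapply(setdiff, dn, both, SIMPLIFY = FALSE)
  }
  empty <- lengths(up) + lengths(dn) == 0L
  if (any(empty)) {
    abort(paste0("signatures with no genes after normalization: ",
                 paste(signatures$signature_id[empty], collapse = ", ")))
  }
  signatures$up_genes <- up
  signatures$down_genes <- dn
  as_tibble(signatures)
}

#' Swap up and down gene sets
#'
#' Exchanges the two directions of every signature; used for the
#' antisymmetry property of the signed Jaccard index.
#'
#' @param signatures Signature tibble.
#' @return Signature tibble with `up_genes` and `down_genes` exchanged.
#' @export
swap_up_down <- function(signatures) {
  tmp <- signatures$up_genes
  signatures$up_genes <- signatures$down_genes
  signatures$down_genes <- tmp
  signatures
}
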