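#' Build an indication table
#'
#' A drug-to-disease mapping curated from drug-label "indications and
#' usage" sections. Names are normalized identically to signature entity
#' names so that joins are exact.
#'
#' @param drug,disease Equal-length character vectors; each row states that
#'   `drug` is indicated for `disease`.
#' @return Tibble of class `ges_indications` with distinct normalized rows.
#' @export
indication_table <- function(drug, disease) {
  out <- distinct(tibble(drug = normalize_entity_name(drug),
                         disease = normalize_entity_name(disease)))
  class(out) <- c("ges_indications", class(out))
  out
}

#' Read an indication table from two-column TSV
#'
#' @param path TSV path with columns `drug`, `disease`.
#' @return A `ges_indications` tibble.
#' @export
read_indication_table <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("drug", "disease") %in% names(df))) {
    abort("indication table needs columns: drug, disease")
  }
  indication_table(df$drug, df$disease)
}

#' Drop signatures without any indicated partner
#'
#' A drug signature is analyzable only if its drug is indicated for at
#' least one disease that still has signatures, and a disease signature
#' only if some retained drug is indicated for it (e.g. a local-anesthetic
#' drug whose sole indication has no disease signature cannot be paired and
#' is removed). Removing one side can orphan the other, so pruning iterates
#' to a fixed point.
#'
#' @param signatures Filtered signature tibble.
#' @param indications A `ges_indications` table.
#' @return Pruned signature tibble with attribute `"n_pruned"`.
#' @export
prune_unpaired <- function(signatures, indications) {
  n0 <- nrow(signatures)
  repeat {
    drugs <- unique(signatures$entity_name[signatures$entity_kind == "drug"])
    diseases <- unique(
      signatures$entity_name[signatures$entity_kind == "disease"])
    ind <- indications[indications$drug %in% drugs &
                         indications$disease %in% diseases, , drop = FALSE]
    keep <- (signatures$entity_kind == "drug" &
               signatures$entity_name %in% ind$drug) |
            (signatures$entity_kind == "disease" &
               signatures$entity_name %in% ind$disease)
    if (all(keep)) break
    signatures <- signatures[keep, , drop = FALSE]
    if (nrow(signatures) == 0L) break
  }
  if (nrow(signatures) == 0L ||
      !any(signatures$entity_kind == "drug") ||
      !any(signatures$entity_kind == "disease")) {
    abort("no analyzable pairs: every signature lost its indication partner")
  }
  attr(signatures, "n_pruned") <- n0 - nrow(signatures)
  signatures
}

#' Aggregate signature-level SJIs to unique drug-disease pairs
#'
#' When a drug and a disease each have several signatures, every signature
#' combination is scored and the unique pair's overall score is the
#' unweighted arithmetic mean of those scores. Each pair is labelled
#' `indicated` when the disease appears among the drug's indications; all
#' remaining pairs form the random control group (no sampling).
#'
#' @param sji_table Output of [pairwise_sji_matrix()].
#' @param signatures Signature tibble covering all ids in `sji_table`.
#' @param indications A `ges_indications` table.
#' @return Tibble with one row per `(drug, disease)`: `drug`, `disease`,
#'   `n_signature_pairs`, `sji_values` (list-column), `mean_sji`,
#'   `indicated`.
#' @export
build_unique_pairs <- function(sji_table, signatures, indications) {
  lookup <- setNames(signatures$entity_name, signatures$signature_id)
  miss <- setdiff(c(sji_table$drug_signature_id,
                    sji_table$disease_signature_id), names(lookup))
  if (length(miss)) {
    abort(paste0("sji table references unknown signatures: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  df <- tibble(
    drug = unname(lookup[sji_table$drug_signature_id]),
    disease = unname(lookup[sji_table$disease_signature_id]),
    sji = sji_table$sji
  )
  pairs <- df |>
    group_by(.data$drug, .data$disease) |>
    summarise(
      n_signature_pairs = n(),
      sji_values = list(.data$sji),
      mean_sji = mean(.data$sji),
      .groups = "drop"
    ) |>
    arrange(.data$drug, .data$disease)
  key <- paste(indications$drug, indications$disease, sep = "\r")
  pairs$indicated <- paste(pairs$drug, pairs$disease, sep = "\r") %in% key
  pairs
}

#' Split unique pairs into indicated and control groups
#'
#' @param pairs Output of [build_unique_pairs()].
#' @return List with tibbles `indicated` and `control`; their row counts
#'   always sum to `nrow(pairs)`.
#' @export
split_by_indication <- function(pairs) {
  if (!any(pairs$indicated)) {
    abort("no indicated pairs: indicated-vs-control analysis is undefined")
  }
  if (all(pairs$indicated)) {
    warn("every pair is indicated; the control group is empty")
  }
  list(indicated = pairs[pairs$indicated, , drop = FALSE],
       control = pairs[!pairs$indicated, , drop = FALSE])
}

#' Write a unique-pair table as TSV
#'
#' @param pairs Output of [build_unique_pairs()].
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  write_tsv_file(pairs[, c("drug", "disease", "n_signature_pairs",
                           "mean_sji", "indicated")], path)
}
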