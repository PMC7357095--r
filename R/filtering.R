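#' Default organism synonym table
#'
#' Maps common organism spellings to canonical lowercase labels so that an
#' allow-list of `"human"` also admits records labelled `"Homo sapiens"`.
#' Shipped as a plain TSV in `inst/extdata/organism_synonyms.tsv`.
#'
#' @return Tibble with columns `synonym`, `canonical`.
#' @export
default_organism_synonyms <- function() {
  path <- system.file("extdata", "organism_synonyms.tsv",
                      package = "gesreversal")
  if (nzchar(path)) {
    read_tsv_file(path)
  } else {
    tibble(synonym = c("homo sapiens", "h. sapiens", "mus musculus",
                       "m. musculus", "rattus norvegicus"),
           canonical = c("human", "human", "mouse", "mouse", "rat"))
  }
}

#' Inclusion-filter configuration
#'
#' Bundles the signature inclusion criteria: allowed organisms (matched
#' case-insensitively through a synonym table), the set of approved drug
#' names (an explicit input list, e.g. an FDA-approval snapshot — never an
#' API call), explicitly excluded mis-specified signature ids, and the
#' policy for series that contributed both drug and disease signatures.
#'
#' @param approved_drugs Character vector of approved drug names. Must be
#'   non-empty whenever drug signatures are being filtered.
#' @param allowed_organisms Character vector, default `"human"`.
#' @param excluded_ids Signature ids to drop as mis-specified.
#' @param dual_label_policy One of `"keep_disease"` (default, drop the drug
#'   signatures of a dual-labelled series), `"keep_drug"`, `"drop_both"`.
#' @param organism_synonyms Synonym table as from
#'   [default_organism_synonyms()].
#' @return A `ges_filter_config` list.
#' @export
filter_config <- function(approved_drugs = character(),
                          allowed_organisms = "human",
                          excluded_ids = character(),
                          dual_label_policy = c("keep_disease", "keep_drug",
                                                "drop_both"),
                          organism_synonyms = default_organism_synonyms()) {
  structure(
    list(
      approved_drugs = normalize_entity_name(approved_drugs),
      allowed_organisms = tolower(trimws(allowed_organisms)),
      excluded_ids = as.character(excluded_ids),
      dual_label_policy = match.arg(dual_label_policy),
      organism_synonyms = organism_synonyms
    ),
    class = "ges_filter_config"
  )
}

canonical_organism <- function(x, synonyms) {
  x <- tolower(trimws(x))
  m <- match(x, synonyms$synonym)
  ifelse(is.na(m), x, synonyms$canonical[m])
}

#' Apply the signature inclusion protocol
#'
#' Removes, in order: signatures from disallowed organisms; drug signatures
#' whose drug is not on the approved list; signatures on the explicit
#' exclusion list (mis-specified entries); then resolves dual-labelled
#' series via [resolve_dual_labels()]. The returned report accounts for
#' every input signature exactly once (retained + sum of exclusions equals
#' the input count); the `no_indication_partner` reason is filled in later
#' by [prune_unpaired()] bookkeeping in the pipeline.
#'
#' @param signatures Validated signature tibble.
#' @param config A [filter_config()].
#' @return List with elements `signatures` (retained tibble) and `report`
#'   (a `ges_filter_report`).
#' @export
apply_inclusion_filters <- function(signatures, config) {
  stopifnot(inherits(config, "ges_filter_config"))
  if (any(signatures$entity_kind == "drug") &&
      length(config$approved_drugs) == 0L) {
    abort("approved_drugs must be non-empty when drug signatures are present")
  }
  n_input <- nrow(signatures)
  reason <- rep(NA_character_, n_input)

  org <- canonical_organism(signatures$organism, config$organism_synonyms)
  reason[is.na(reason) & !(org %in% config$allowed_organisms)] <- "non_human"

  not_approved <- signatures$entity_kind == "drug" &
    !(signatures$entity_name %in% config$approved_drugs)
  reason[is.na(reason) & not_approved] <- "not_approved"

  reason[is.na(reason) &
           signatures$signature_id %in% config$excluded_ids] <- "mis_specified"

  surviving <- signatures[is.na(reason), , drop = FALSE]
  resolved <- resolve_dual_labels(surviving, config$dual_label_policy)
  dual_dropped <- setdiff(surviving$signature_id, resolved$signature_id)
  reason[signatures$signature_id %in% dual_dropped] <- "dual_label"

  report <- filter_report(
    n_input = n_input,
    exclusions = c(
      non_human = sum(reason == "non_human", na.rm = TRUE),
      not_approved = sum(reason == "not_approved", na.rm = TRUE),
      mis_specified = sum(reason == "mis_specified", na.rm = TRUE),
      dual_label = sum(reason == "dual_label", na.rm = TRUE),
      no_indication_partner = 0L
    ),
    retained_drugs = sum(resolved$entity_kind == "drug"),
    retained_diseases = sum(resolved$entity_kind == "disease")
  )
  list(signatures = resolved, report = report)
}

filter_report <- function(n_input, exclusions, retained_drugs,
                          retained_diseases) {
  structure(
    list(n_input = as.integer(n_input),
         exclusions = vapply(exclusions, as.integer, integer(1)),
         retained_drugs = as.integer(retained_drugs),
         retained_diseases = as.integer(retained_diseases)),
    class = "ges_filter_report"
  )
}

#' @export
print.ges_filter_report <- function(x, ...) {
  cat("Signature inclusion report\n")
  cat("  input signatures:", x$n_input, "\n")
  for (nm in names(x$exclusions)) {
    cat(sprintf("  excluded %-22s %d\n", paste0(nm, ":"), x$exclusions[[nm]]))
  }
  cat("  retained drug signatures:   ", x$retained_drugs, "\n")
  cat("  retained disease signatures:", x$retained_diseases, "\n")
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `ges_filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  df <- tibble(
    field = c("input", paste0("excluded_", names(report$exclusions)),
              "retained_drug_signatures", "retained_disease_signatures"),
    count = c(report$n_input, unname(report$exclusions),
              report$retained_drugs, report$retained_diseases)
  )
  write_tsv_file(df, path)
}

#' Resolve series labelled as both drug and disease
#'
#' Signatures for a drug treatment and for a disease extracted from the
#' same assay series would bias the similarity (shared measurement), so one
#' side is dropped. The default policy keeps the disease labels, matching
#' the curated resolution of the source collection; genuinely mis-specified
#' entries are handled separately via `excluded_ids`.
#'
#' @param signatures Signature tibble carrying `series_id`.
#' @param policy `"keep_disease"`, `"keep_drug"` or `"drop_both"`.
#' @return Signature tibble with the dual-labelled side(s) removed.
#' @export
resolve_dual_labels <- function(signatures,
                                policy = c("keep_disease", "keep_drug",
                                           "drop_both")) {
  policy <- match.arg(policy)
  if (nrow(signatures) == 0L) return(signatures)
  by_series <- split(signatures$entity_kind, signatures$series_id)
  dual <- names(by_series)[vapply(by_series, function(k) {
    all(c("drug", "disease") %in% k)
  }, logical(1))]
  dual <- dual[!is.na(dual)]
  if (length(dual) == 0L) return(signatures)
  in_dual <- !is.na(signatures$series_id) & signatures$series_id %in% dual
  drop <- switch(policy,
    keep_disease = in_dual & signatures$entity_kind == "drug",
    keep_drug = in_dual & signatures$entity_kind == "disease",
    drop_both = in_dual
  )
  signatures[!drop, , drop = FALSE]
}
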