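#' Target classes defining chemotherapy drugs
#'
#' Drugs whose main therapeutic target falls into one of these classes are
#' labelled chemotherapy: DNA cross-linking/alkylation, DNA ligase, DNA
#' methyltransferase, DNA polymerase, human DNA topoisomerase,
#' micro-tubules, nucleotide synthesis, thymidylate synthase.
#'
#' @return Character vector of class labels.
#' @export
default_chemo_target_classes <- function() {
  c("DNA cross-linking/alkylation", "DNA/ligase", "DNA/methyltransferase",
    "DNA/polymerase", "DNA/topoisomerase-human", "micro-tubules",
    "nucleotide synthesis", "Thymidylate synthase")
}

#' Assemble an annotation bundle
#'
#' Holds the user-supplied annotation tables that drive the five subgroup
#' categories: main therapeutic targets per drug, an optional raw-target to
#' subfamily grouping (e.g. the three beta-adrenergic receptors collapsing
#' to one subfamily), the set of targets that are human transcription
#' factors, the set of non-human targets (bacterial/viral proteins or
#' structures), the chemotherapy-defining target classes, ATC level-3
#' codes per drug with an optional route-unification map, and the ICD-11
#' level-1 class per disease. All content is curated input, not queried.
#'
#' @param drug_targets Tibble `drug`, `target` (one row per main target).
#' @param icd11_level1 Tibble `disease`, `disease_class`.
#' @param atc3 Tibble `drug`, `atc3`.
#' @param target_grouping Optional tibble `target`, `group`; targets not
#'   listed pass through unchanged.
#' @param tf_targets Character vector of targets that are human TFs.
#' @param nonhuman_targets Character vector of non-human targets.
#' @param chemo_target_classes Character vector; default
#'   [default_chemo_target_classes()].
#' @param atc_unification Optional tibble `atc3`, `unified` mapping
#'   route-specific codes to their systemic-use variant.
#' @return A `ges_annotation_bundle` list.
#' @export
annotation_bundle <- function(drug_targets, icd11_level1, atc3,
                              target_grouping = NULL,
                              tf_targets = character(),
                              nonhuman_targets = character(),
                              chemo_target_classes =
                                default_chemo_target_classes(),
                              atc_unification = NULL) {
  stopifnot(all(c("drug", "target") %in% names(drug_targets)),
            all(c("disease", "disease_class") %in% names(icd11_level1)),
            all(c("drug", "atc3") %in% names(atc3)))
  drug_targets$drug <- normalize_entity_name(drug_targets$drug)
  icd11_level1$disease <- normalize_entity_name(icd11_level1$disease)
  atc3$drug <- normalize_entity_name(atc3$drug)
  structure(
    list(drug_targets = as_tibble(drug_targets),
         icd11_level1 = as_tibble(icd11_level1),
         atc3 = as_tibble(atc3),
         target_grouping = target_grouping,
         tf_targets = tf_targets,
         nonhuman_targets = nonhuman_targets,
         chemo_target_classes = chemo_target_classes,
         atc_unification = atc_unification),
    class = "ges_annotation_bundle"
  )
}

apply_target_grouping <- function(targets, grouping) {
  if (is.null(grouping)) return(targets)
  m <- match(targets, grouping$target)
  ifelse(is.na(m), targets, grouping$group[m])
}

apply_atc_unification <- function(codes, unification) {
  if (is.null(unification)) return(codes)
  m <- match(codes, unification$atc3)
  ifelse(is.na(m), codes, unification$unified[m])
}

#' Assign the transcription-factor level of each drug
#'
#' `directly` when any main therapeutic target is a human transcription
#' factor; `non_human` when every main target is a non-human protein or
#' structure (e.g. viral or bacterial); `not_directly` otherwise (human
#' proteins or DNA structures that are not TFs).
#'
#' @param drug_targets Tibble `drug`, `target`.
#' @param tf_targets Character vector of human-TF targets.
#' @param nonhuman_targets Character vector of non-human targets.
#' @return Tibble `drug`, `tf_level`.
#' @export
assign_tf_level <- function(drug_targets, tf_targets,
                            nonhuman_targets = character()) {
  drug_targets |>
    group_by(.data$drug) |>
    summarise(tf_level = {
      t <- .data$target
      if (any(t %in% tf_targets)) "directly"
      else if (length(t) > 0L && all(t %in% nonhuman_targets)) "non_human"
      else "not_directly"
    }, .groups = "drop")
}

#' Assign chemotherapy status of each drug
#'
#' A drug is chemotherapy when any of its main target classes is on the
#' chemotherapy list. A drug whose annotated main targets span both chemo
#' and non-chemo classes (context-dependent mechanism, e.g. an
#' antimetabolite also used as an immunosuppressant) carries both labels.
#'
#' @param drug_targets Tibble `drug`, `target` (target-class labels).
#' @param chemo_target_classes Character vector of chemotherapy-defining
#'   classes.
#' @return Tibble `drug`, `chemo_label` (rows in `{"chemo", "non_chemo"}`;
#'   one or two rows per drug).
#' @export
assign_chemotherapy <- function(drug_targets,
                                chemo_target_classes =
                                  default_chemo_target_classes()) {
  drug_targets |>
    group_by(.data$drug) |>
    summarise(labels = list({
      t <- .data$target
      c(if (any(t %in% chemo_target_classes)) "chemo",
        if (any(!(t %in% chemo_target_classes))) "non_chemo")
    }), .groups = "drop") |>
    tidyr::unnest(cols = "labels") |>
    rename(chemo_label = "labels")
}

#' Build the pair-by-subgroup assignment table
#'
#' Emits one row per (unique pair, category, applicable label) across the
#' five categories: `disease_class` (ICD-11 level 1 of the disease),
#' `target` (drug main-target subfamilies, after grouping), `tf_level`,
#' `chemotherapy`, and `atc` (level-3 codes, route-unified). `disease_class`
#' and `tf_level` assign exactly one label per annotated pair; the other
#' three may multi-label (multi-target and multi-ATC drugs, dual-status
#' chemotherapy). Pairs lacking an annotation in one category are dropped
#' from that category only and reported via a message.
#'
#' @param pairs Unique-pair tibble from [build_unique_pairs()].
#' @param bundle A [annotation_bundle()].
#' @return Tibble `drug`, `disease`, `category`, `subgroup_label`.
#' @export
build_subgroup_table <- function(pairs, bundle) {
  stopifnot(inherits(bundle, "ges_annotation_bundle"))
  key <- pairs[, c("drug", "disease")]

  dz <- inner_join(key, bundle$icd11_level1, by = "disease") |>
    mutate(category = "disease_class", subgroup_label = .data$disease_class)

  tg <- bundle$drug_targets |>
    mutate(subgroup_label =
             apply_target_grouping(.data$target, bundle$target_grouping)) |>
    distinct(.data$drug, .data$subgroup_label)
  tgt <- inner_join(key, tg, by = "drug",
                    relationship = "many-to-many") |>
    mutate(category = "target")

  tf <- assign_tf_level(bundle$drug_targets, bundle$tf_targets,
                        bundle$nonhuman_targets)
  tfl <- inner_join(key, tf, by = "drug") |>
    mutate(category = "tf_level", subgroup_label = .data$tf_level)

  ch <- assign_chemotherapy(bundle$drug_targets, bundle$chemo_target_classes)
  chl <- inner_join(key, ch, by = "drug", relationship = "many-to-many") |>
    mutate(category = "chemotherapy", subgroup_label = .data$chemo_label)

  atc <- bundle$atc3 |>
    mutate(subgroup_label =
             apply_atc_unification(.data$atc3, bundle$atc_unification)) |>
    distinct(.data$drug, .data$subgroup_label)
  atcl <- inner_join(key, atc, by = "drug", relationship = "many-to-many") |>
    mutate(category = "atc")

  out <- bind_rows(
    dz[, c("drug", "disease", "category", "subgroup_label")],
    tgt[, c("drug", "disease", "category", "subgroup_label")],
    tfl[, c("drug", "disease", "category", "subgroup_label")],
    chl[, c("drug", "disease", "category", "subgroup_label")],
    atcl[, c("drug", "disease", "category", "subgroup_label")]
  ) |>
    distinct() |>
    arrange(.data$category, .data$subgroup_label, .data$drug, .data$disease)

  for (cat in c("disease_class", "target", "tf_level", "chemotherapy",
                "atc")) {
    covered <- out[out$category == cat, c("drug", "disease")]
    missing <- anti_join(key, covered, by = c("drug", "disease"))
    if (nrow(missing) > 0L) {
      inform(paste0(nrow(missing), " pair(s) unannotated in category '",
                    cat, "' and omitted from it"))
    }
  }
  out
}
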