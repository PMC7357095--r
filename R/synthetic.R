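disease_class_pool <- c(
  "diseases of the immune system", "neoplasms",
  "diseases of the nervous system", "certain infectious or parasitic diseases",
  "endocrine, nutritional or metabolic diseases", "diseases of the skin",
  "diseases of the circulatory system", "diseases of the respiratory system",
  "diseases of the digestive system",
  "diseases of the blood or blood-forming organs",
  "diseases of the musculoskeletal system or connective tissue"
)

target_pool <- tibble::tibble(
  target = c("Interferon receptor", "glucocorticoid receptor",
             "HMG-CoA reductase", "micro-tubules", "DNA/polymerase",
             "tyrosine kinase", "16S ribosomal RNA",
             "Beta-1 adrenergic receptor"),
  is_tf = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  nonhuman = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
)

atc_pool <- c(
  "L03 immunostimulants", "H02 corticosteroids for systemic use",
  "C10 lipid modifying agents", "L01 plant alkaloids",
  "J05 direct acting antivirals", "L01 protein kinase inhibitors",
  "J01 tetracyclines", "C07 beta blocking agents"
)

#' Configuration of a synthetic study
#'
#' Defines the conditions a generated study emulates: a gene universe,
#' drug and disease rosters with one-to-several signatures each, a sparse
#' FDA-style indication table, the five annotation categories, and a
#' planted reversal: drug signatures of drugs indicated for a disease in a
#' sensitive subgroup copy a fraction `reversal_strength` of that
#' disease's genes with the direction flipped (treatment reverses disease
#' expression), while all other signature content is direction-neutral.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_genes Gene universe size.
#' @param n_drugs,n_diseases Roster sizes.
#' @param signatures_per_entity Integer range `c(min, max)`.
#' @param signature_size Range of genes per direction, `c(min, max)`.
#' @param indication_density Probability an arbitrary drug-disease pair is
#'   indicated.
#' @param n_forced_sensitive_indications Indications guaranteed to land in
#'   the sensitive disease class, so that the planted subgroup is always
#'   testable.
#' @param sensitive_subgroups Disease-class labels receiving the planted
#'   reversal.
#' @param reversal_strength Fraction rho in \[0, 1\] of the target
#'   disease's genes copied flipped into each indicated drug signature;
#'   0 disables planting entirely.
#' @param background_overlap Fraction of a non-planted signature drawn
#'   from the pooled disease gene set (random direction).
#' @param n_disease_classes,n_target_groups,n_atc_classes Number of
#'   distinct labels used per annotation category.
#' @return A validated `ges_sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 1000L, n_drugs = 20L,
                              n_diseases = 25L,
                              signatures_per_entity = c(1L, 3L),
                              signature_size = c(20L, 50L),
                              indication_density = 0.05,
                              n_forced_sensitive_indications = 3L,
                              sensitive_subgroups =
                                "diseases of the immune system",
                              reversal_strength = 0,
                              background_overlap = 0.02,
                              n_disease_classes = 5L, n_target_groups = 6L,
                              n_atc_classes = 6L) {
  cfg <- structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
         signatures_per_entity = as.integer(signatures_per_entity),
         signature_size = as.integer(signature_size),
         indication_density = indication_density,
         n_forced_sensitive_indications =
           as.integer(n_forced_sensitive_indications),
         sensitive_subgroups = sensitive_subgroups,
         reversal_strength = reversal_strength,
         background_overlap = background_overlap,
         n_disease_classes = as.integer(n_disease_classes),
         n_target_groups = as.integer(n_target_groups),
         n_atc_classes = as.integer(n_atc_classes)),
    class = "ges_sim_config"
  )
  with(cfg, {
    if (length(signatures_per_entity) != 2L ||
        signatures_per_entity[1] > signatures_per_entity[2] ||
        signatures_per_entity[1] < 1L) {
      abort("signatures_per_entity must be a non-empty range c(min, max)")
    }
    if (length(signature_size) != 2L ||
        signature_size[1] > signature_size[2] || signature_size[1] < 1L) {
      abort("signature_size must be a non-empty range c(min, max)")
    }
    if (2L * signature_size[2] > n_genes) {
      abort("signature_size x 2 must not exceed n_genes")
    }
    if (indication_density <= 0 || indication_density >= 1) {
      abort("indication_density must lie in (0, 1)")
    }
    if (reversal_strength < 0 || reversal_strength > 1) {
      abort("reversal_strength must lie in [0, 1]")
    }
    if (background_overlap < 0 || background_overlap > 1) {
      abort("background_overlap must lie in [0, 1]")
    }
    if (n_disease_classes > length(disease_class_pool) ||
        n_target_groups > nrow(target_pool) ||
        n_atc_classes > length(atc_pool)) {
      abort("requested more annotation labels than the label pools hold")
    }
  })
  cfg
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

#' Generate a complete synthetic study
#'
#' Produces signatures, an indication table, an annotation bundle and a
#' ground-truth record, fully determined by the config seed. Disease
#' signatures are drawn uniformly from the gene universe. Drugs indicated
#' for a disease of a sensitive class build every one of their signatures
#' against that disease's first signature: a fraction `reversal_strength`
#' of its up (down) genes enters the drug signature's down (up) set, the
#' remainder is random and avoids the target disease's genes. All other
#' drug signatures are random apart from a `background_overlap` fraction
#' drawn from the pooled disease genes with random direction. Each
#' generation stage uses a deterministically derived child seed, so adding
#' a stage never perturbs earlier ones.
#'
#' @param config A [simulation_config()].
#' @return List of class `ges_synthetic_study`: `signatures`,
#'   `indications`, `annotations`, `ground_truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "ges_sim_config"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  diseases <- sprintf("disease %02d", seq_len(config$n_diseases))
  drugs <- sprintf("drug %02d", seq_len(config$n_drugs))
  classes <- disease_class_pool[seq_len(config$n_disease_classes)]
  disease_class <- classes[(seq_len(config$n_diseases) - 1L) %%
                             length(classes) + 1L]

  # --- disease signatures -------------------------------------------------
  set.seed(stage_seed(config$seed, "diseases"))
  dz_rows <- list(); k <- 0L
  for (i in seq_along(diseases)) {
    for (s in seq_len(sample_range(config$signatures_per_entity))) {
      k <- k + 1L
      n_up <- sample_range(config$signature_size)
      n_dn <- sample_range(config$signature_size)
      g <- sample(genes, n_up + n_dn)
      dz_rows[[k]] <- ges_signature(
        sprintf("dz:%03d", k), up_genes = g[seq_len(n_up)],
        down_genes = g[-seq_len(n_up)], entity_kind = "disease",
        entity_name = diseases[i],
        series_id = sprintf("GSESIMD%03d", k))
    }
  }
  dz_sigs <- bind_rows(dz_rows)

  # --- indications --------------------------------------------------------
  set.seed(stage_seed(config$seed, "indications"))
  sensitive_dz <- diseases[disease_class %in% config$sensitive_subgroups]
  forced <- tibble(drug = character(), disease = character())
  if (config$n_forced_sensitive_indications > 0L && length(sensitive_dz)) {
    nf <- min(config$n_forced_sensitive_indications, config$n_drugs)
    forced <- tibble(
      drug = drugs[seq_len(nf)],
      disease = sensitive_dz[(seq_len(nf) - 1L) %% length(sensitive_dz) + 1L]
    )
  }
  rand_ind <- tidyr::expand_grid(drug = drugs, disease = diseases)
  rand_ind <- rand_ind[stats::runif(nrow(rand_ind)) <
                         config$indication_density, , drop = FALSE]
  indications <- indication_table(c(forced$drug, rand_ind$drug),
                                  c(forced$disease, rand_ind$disease))

  # --- annotations --------------------------------------------------------
  tgt <- target_pool[seq_len(config$n_target_groups), , drop = FALSE]
  drug_target <- tgt$target[(seq_len(config$n_drugs) - 1L) %%
                              nrow(tgt) + 1L]
  annotations <- annotation_bundle(
    drug_targets = tibble(drug = drugs, target = drug_target),
    icd11_level1 = tibble(disease = diseases, disease_class = disease_class),
    atc3 = tibble(drug = drugs,
                  atc3 = atc_pool[(seq_len(config$n_drugs) - 1L) %%
                                    config$n_atc_classes + 1L]),
    target_grouping = tibble(
      target = c("Beta-1 adrenergic receptor", "Beta-2 adrenergic receptor",
                 "Beta-3 adrenergic receptor"),
      group = "Beta adrenergic receptors"),
    tf_targets = tgt$target[tgt$is_tf],
    nonhuman_targets = tgt$target[tgt$nonhuman]
  )

  # --- drug signatures (with planted reversal) ----------------------------
  set.seed(stage_seed(config$seed, "drugs"))
  dz_gene_pool <- unique(c(unlist(dz_sigs$up_genes),
                           unlist(dz_sigs$down_genes)))
  first_dz_sig <- function(dz_name) {
    dz_sigs[dz_sigs$entity_name == dz_name, ][1, ]
  }
  rho <- config$reversal_strength
  dr_rows <- list(); planted <- character(); sensitive_drugs <- character()
  planted_pairs <- list()
  k <- 0L
  for (i in seq_along(drugs)) {
    my_ind <- sort(indications$disease[indications$drug == drugs[i]])
    target_dz <- my_ind[my_ind %in% sensitive_dz][1]
    plant <- !is.na(target_dz) && rho > 0
    if (!is.na(target_dz)) sensitive_drugs <- c(sensitive_drugs, drugs[i])
    if (plant) {
      planted_pairs[[length(planted_pairs) + 1L]] <-
        tibble(drug = drugs[i], disease = target_dz)
    }
    for (s in seq_len(sample_range(config$signatures_per_entity))) {
      k <- k + 1L
      n_up <- sample_range(config$signature_size)
      n_dn <- sample_range(config$signature_size)
      if (plant) {
        ref <- first_dz_sig(target_dz)
        ref_up <- ref$up_genes[[1]]; ref_dn <- ref$down_genes[[1]]
        up_plant <- sample(ref_dn, round(rho * length(ref_dn)))
        dn_plant <- sample(ref_up, round(rho * length(ref_up)))
        avoid <- c(ref_up, ref_dn)
        free <- setdiff(genes, avoid)
        fill_up <- sample(free, max(0L, n_up - length(up_plant)))
        fill_dn <- sample(setdiff(free, fill_up),
                          max(0L, n_dn - length(dn_plant)))
        up <- c(up_plant, fill_up); dn <- c(dn_plant, fill_dn)
        planted <- c(planted, up_plant, dn_plant)
      } else {
        n_bg <- round(config$background_overlap * (n_up + n_dn))
        bg <- sample(dz_gene_pool, min(n_bg, length(dz_gene_pool)))
        rest <- sample(setdiff(genes, bg), n_up + n_dn - length(bg))
        g <- sample(c(bg, rest))
        up <- g[seq_len(n_up)]; dn <- g[-seq_len(n_up)]
      }
      dr_rows[[k]] <- ges_signature(
        sprintf("drug:%03d", k), up_genes = up, down_genes = dn,
        entity_kind = "drug", entity_name = drugs[i],
        series_id = sprintf("GSESIMR%03d", k))
    }
  }
  signatures <- validate_signatures(bind_rows(bind_rows(dr_rows), dz_sigs))

  sens_pairs <- indications[indications$disease %in% sensitive_dz, ,
                            drop = FALSE]
  # bookkeeping after indication-partner pruning: the analyzable crossing
  kept <- prune_fixed_point(signatures, indications)
  drugs_kept <- unique(kept$entity_name[kept$entity_kind == "drug"])
  dz_kept <- unique(kept$entity_name[kept$entity_kind == "disease"])
  ind_kept <- indications[indications$drug %in% drugs_kept &
                            indications$disease %in% dz_kept, , drop = FALSE]
  ground_truth <- list(
    planted_genes = sort(unique(planted)),
    sensitive_diseases = sensitive_dz,
    sensitive_drugs = sort(unique(sensitive_drugs)),
    sensitive_pairs = sens_pairs,
    planted_pairs = bind_rows(planted_pairs),
    sensitive_subgroups = config$sensitive_subgroups,
    n_indicated_pairs = nrow(ind_kept),
    n_unique_pairs = length(drugs_kept) * length(dz_kept),
    reversal_strength = rho,
    seed = config$seed
  )
  structure(
    list(signatures = signatures, indications = indications,
         annotations = annotations, ground_truth = ground_truth,
         config = config),
    class = "ges_synthetic_study"
  )
}

#' Materialize a synthetic study as pipeline input files
#'
#' Writes the exact formats the pipeline consumes: `signatures.json`
#' (CREEDS dialect), `indications.tsv`, an `annotations/` directory of
#' TSVs, `ground_truth.json` and `sim_config.yaml`.
#'
#' @param config A [simulation_config()] (or a YAML path holding its
#'   fields).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_study_dir <- function(config, dir) {
  if (is.character(config)) {
    fields <- yaml::read_yaml(config)
    config <- do.call(simulation_config, fields)
  }
  study <- generate_study(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_creeds_json(study$signatures, file.path(dir, "signatures.json"))
  write_tsv_file(study$indications, file.path(dir, "indications.tsv"))
  write_annotation_bundle(study$annotations, file.path(dir, "annotations"))
  jsonlite::write_json(study$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Write an annotation bundle as a directory of TSV/text files
#'
#' @param bundle A [annotation_bundle()].
#' @param dir Output directory.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(bundle$drug_targets, file.path(dir, "drug_targets.tsv"))
  write_tsv_file(bundle$icd11_level1, file.path(dir, "disease_classes.tsv"))
  write_tsv_file(bundle$atc3, file.path(dir, "atc3.tsv"))
  if (!is.null(bundle$target_grouping)) {
    write_tsv_file(bundle$target_grouping,
                   file.path(dir, "target_grouping.tsv"))
  }
  if (!is.null(bundle$atc_unification)) {
    write_tsv_file(bundle$atc_unification,
                   file.path(dir, "atc_unification.tsv"))
  }
  writeLines(bundle$tf_targets, file.path(dir, "tf_targets.txt"))
  writeLines(bundle$nonhuman_targets, file.path(dir, "nonhuman_targets.txt"))
  writeLines(bundle$chemo_target_classes,
             file.path(dir, "chemo_target_classes.txt"))
  invisible(dir)
}

#' Read an annotation bundle from a directory
#'
#' Inverse of [write_annotation_bundle()].
#'
#' @param dir Directory holding the annotation files.
#' @return A `ges_annotation_bundle`.
#' @export
read_annotation_bundle <- function(dir) {
  opt_tsv <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) read_tsv_file(p) else NULL
  }
  opt_lines <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) readLines(p, warn = FALSE) else character()
  }
  chemo <- opt_lines("chemo_target_classes.txt")
  annotation_bundle(
    drug_targets = read_tsv_file(file.path(dir, "drug_targets.tsv")),
    icd11_level1 = read_tsv_file(file.path(dir, "disease_classes.tsv")),
    atc3 = read_tsv_file(file.path(dir, "atc3.tsv")),
    target_grouping = opt_tsv("target_grouping.tsv"),
    atc_unification = opt_tsv("atc_unification.tsv"),
    tf_targets = opt_lines("tf_targets.txt"),
    nonhuman_targets = opt_lines("nonhuman_targets.txt"),
    chemo_target_classes = if (length(chemo)) chemo else
      default_chemo_target_classes()
  )
}

#' Packaged small fixture study exercising every filter branch
#'
#' A ~20-drug by ~25-disease synthetic study augmented with one signature
#' for each exclusion path of the inclusion protocol: a mouse-labelled
#' signature, a signature of a drug absent from the approved list, an
#' explicitly excluded mis-specified signature, a series carrying both a
#' drug and a disease label (resolved keep-disease), and an approved drug
#' whose only indication has no disease signature in the data (pruned at
#' the pairing step). `metadata` records the expected filter-report counts
#' and the indicated/control split of the retained study.
#'
#' @return List: `signatures`, `indications`, `annotations`,
#'   `filter_config`, `metadata`.
#' @export
make_fixture_bundle <- function() {
  base <- generate_study(simulation_config(
    seed = 776L, n_genes = 400L, n_drugs = 17L, n_diseases = 23L,
    signature_size = c(10L, 20L), reversal_strength = 0.6
  ))
  sigs <- base$signatures
  genes <- sprintf("G%05d", 1:400)

  extras <- bind_rows(
    ges_signature("drug:900", up_genes = genes[1:10],
                  down_genes = genes[11:20], entity_kind = "drug",
                  entity_name = "murine compound", organism = "Mus musculus",
                  series_id = "GSEFIXM1"),
    ges_signature("drug:901", up_genes = genes[21:30],
                  down_genes = genes[31:40], entity_kind = "drug",
                  entity_name = "novel compound x", organism = "human",
                  series_id = "GSEFIXU1"),
    ges_signature("dz:900", up_genes = genes[41:50],
                  down_genes = genes[51:60], entity_kind = "disease",
                  entity_name = "misdisease", organism = "human",
                  series_id = "GSEFIXE1"),
    ges_signature("drug:902", up_genes = genes[61:70],
                  down_genes = genes[71:80], entity_kind = "drug",
                  entity_name = "drug 01", organism = "human",
                  series_id = "GSEFIXD1"),
    ges_signature("dz:901", up_genes = genes[81:90],
                  down_genes = genes[91:100], entity_kind = "disease",
                  entity_name = "disease 01", organism = "human",
                  series_id = "GSEFIXD1"),
    ges_signature("drug:903", up_genes = genes[101:110],
                  down_genes = genes[111:120], entity_kind = "drug",
                  entity_name = "cocaine", organism = "human",
                  series_id = "GSEFIXC1")
  )
  signatures <- validate_signatures(bind_rows(sigs, extras))

  indications <- indication_table(
    c(base$indications$drug, "murine compound", "novel compound x",
      "cocaine"),
    c(base$indications$disease, "disease 02", "disease 03",
      "local anesthesia")
  )
  approved <- sort(unique(c(
    sigs$entity_name[sigs$entity_kind == "drug"],
    "murine compound", "cocaine"
  )))
  cfg <- filter_config(approved_drugs = approved,
                       excluded_ids = "dz:900",
                       dual_label_policy = "keep_disease")

  # expected bookkeeping, derived by set logic at construction time
  retained <- signatures[
    !(signatures$signature_id %in%
        c("drug:900", "drug:901", "dz:900", "drug:902")), , drop = FALSE]
  kept <- prune_fixed_point(retained, indications)
  drugs_kept <- unique(kept$entity_name[kept$entity_kind == "drug"])
  dz_kept <- unique(kept$entity_name[kept$entity_kind == "disease"])
  ind_kept <- indications[indications$drug %in% drugs_kept &
                            indications$disease %in% dz_kept, , drop = FALSE]
  metadata <- list(
    expected_exclusions = c(non_human = 1L, not_approved = 1L,
                            mis_specified = 1L, dual_label = 1L),
    expected_pruned = nrow(retained) - nrow(kept),
    n_unique_pairs = length(drugs_kept) * length(dz_kept),
    n_indicated_pairs = nrow(ind_kept),
    ground_truth = base$ground_truth
  )
  list(signatures = signatures, indications = indications,
       annotations = base$annotations, filter_config = cfg,
       metadata = metadata)
}

# minimal fixed-point used only for fixture bookkeeping
prune_fixed_point <- function(signatures, indications) {
  repeat {
    drugs <- unique(signatures$entity_name[signatures$entity_kind == "drug"])
    dz <- unique(signatures$entity_name[signatures$entity_kind == "disease"])
    ind <- indications[indications$drug %in% drugs &
                         indications$disease %in% dz, , drop = FALSE]
    keep <- (signatures$entity_kind == "drug" &
               signatures$entity_name %in% ind$drug) |
      (signatures$entity_kind == "disease" &
         signatures$entity_name %in% ind$disease)
    if (all(keep)) return(signatures)
    signatures <- signatures[keep, , drop = FALSE]
  }
}
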