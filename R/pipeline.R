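#' Pipeline run configuration
#'
#' Collects the input paths and analysis options for [run_pipeline()].
#'
#' @param signatures_json Path to a CREEDS-style JSON signature file
#'   (alternatively give `gmt_up` + `gmt_down`).
#' @param indications_tsv Path to the two-column indication TSV.
#' @param annotations_dir Directory readable by
#'   [read_annotation_bundle()].
#' @param out_dir Output directory.
#' @param approved_drugs Approved-drug names, or `NULL` to treat every
#'   drug in the data as approved.
#' @param allowed_organisms,excluded_ids,dual_label_policy Passed to
#'   [filter_config()].
#' @param gmt_up,gmt_down Optional GMT pair instead of JSON.
#' @param t_test_variant `"pooled"` or `"welch"`.
#' @param fdr_family `"pooled"` or `"per_category"`.
#' @param fdr_threshold Significance threshold on q (reporting only).
#' @param reversal_subgroup `"auto"` (lowest-q tested subgroup) or a
#'   `list(category =, label =)` selector; `NULL` skips the gene stage.
#' @param top_fraction Fraction of genes exported as most-reversed.
#' @return A `ges_run_config` list (paths validated).
#' @export
run_config <- function(signatures_json = NULL, indications_tsv,
                       annotations_dir, out_dir,
                       approved_drugs = NULL, allowed_organisms = "human",
                       excluded_ids = character(),
                       dual_label_policy = "keep_disease",
                       gmt_up = NULL, gmt_down = NULL,
                       t_test_variant = "pooled", fdr_family = "pooled",
                       fdr_threshold = 0.05,
                       reversal_subgroup = "auto", top_fraction = 0.05) {
  if (is.null(signatures_json) && (is.null(gmt_up) || is.null(gmt_down))) {
    abort("give signatures_json or both gmt_up and gmt_down")
  }
  for (p in c(signatures_json, indications_tsv, annotations_dir, gmt_up,
              gmt_down)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("no such path: ", p))
  }
  structure(
    list(signatures_json = signatures_json, gmt_up = gmt_up,
         gmt_down = gmt_down, indications_tsv = indications_tsv,
         annotations_dir = annotations_dir, out_dir = out_dir,
         approved_drugs = approved_drugs,
         allowed_organisms = allowed_organisms,
         excluded_ids = excluded_ids,
         dual_label_policy = dual_label_policy,
         t_test_variant = t_test_variant, fdr_family = fdr_family,
         fdr_threshold = fdr_threshold,
         reversal_subgroup = reversal_subgroup,
         top_fraction = top_fraction),
    class = "ges_run_config"
  )
}

#' Run the full reversal analysis pipeline
#'
#' Chains the stages filter -> prune -> pairwise SJI -> unique pairs ->
#' subgroup annotation -> overall t-test and slice F tests with BH-FDR ->
#' per-gene reversal scores for the selected subgroup. All tabular outputs
#' are written as TSV into `out_dir` along with a JSON manifest (input
#' checksums, stage counts). The pipeline contains no randomness: rerunning
#' with identical inputs reproduces identical outputs. On error a `FAILED`
#' marker file is written and the condition is rethrown.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ges_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tryCatch(
    run_pipeline_stages(config, out),
    error = function(e) {
      writeLines(conditionMessage(e), file.path(out, "FAILED"))
      abort(paste0("pipeline failed: ", conditionMessage(e)), parent = e)
    }
  )
}

run_pipeline_stages <- function(config, out) {
  inputs <- c(config$signatures_json, config$gmt_up, config$gmt_down,
              config$indications_tsv)
  signatures <- if (!is.null(config$signatures_json)) {
    read_creeds_json(config$signatures_json)
  } else {
    read_gmt_pair(config$gmt_up, config$gmt_down)
  }
  indications <- read_indication_table(config$indications_tsv)
  bundle <- read_annotation_bundle(config$annotations_dir)

  approved <- config$approved_drugs %||%
    unique(signatures$entity_name[signatures$entity_kind == "drug"])
  fcfg <- filter_config(approved_drugs = approved,
                        allowed_organisms = config$allowed_organisms,
                        excluded_ids = config$excluded_ids,
                        dual_label_policy = config$dual_label_policy)
  filtered <- apply_inclusion_filters(signatures, fcfg)
  pruned <- prune_unpaired(filtered$signatures, indications)
  report <- filtered$report
  report$exclusions[["no_indication_partner"]] <-
    attr(pruned, "n_pruned") %||% 0L
  write_filter_report(report, file.path(out, "filter_report.tsv"))

  drugs <- pruned[pruned$entity_kind == "drug", ]
  diseases <- pruned[pruned$entity_kind == "disease", ]
  sji <- pairwise_sji_matrix(drugs, diseases)
  write_sji_matrix(sji, file.path(out, "sji_matrix.tsv"))

  pairs <- build_unique_pairs(sji, pruned, indications)
  write_pair_table(pairs, file.path(out, "unique_pairs.tsv"))
  groups <- split_by_indication(pairs)

  overall <- if (nrow(groups$indicated) >= 2L && nrow(groups$control) >= 2L) {
    overall_t_test(groups$indicated$mean_sji, groups$control$mean_sji,
                   variant = config$t_test_variant)
  } else NULL

  subgroups <- build_subgroup_table(pairs, bundle)
  results <- subgroup_analysis(pairs, subgroups,
                               fdr_family = config$fdr_family)
  write_subgroup_results(results, file.path(out, "subgroup_results.tsv"))

  gene_stage <- NULL
  if (!is.null(config$reversal_subgroup)) {
    sel <- config$reversal_subgroup
    if (identical(sel, "auto")) {
      tested <- results[results$tested & results$n_indicated > 0L, ]
      tested <- tested[order(tested$q_value, tested$p_value), ]
      sel <- if (nrow(tested)) list(category = tested$category[1],
                                    label = tested$subgroup_label[1])
    }
    if (!is.null(sel)) {
      grp <- reversal_input_pairs(pairs, subgroups, pruned,
                                  sel$category, sel$label)
      scores <- g_ir_scores(pruned, grp$indicated, grp$random)
      write_gene_scores(scores, file.path(out, "gene_reversal_scores.tsv"))
      top <- select_top_reversed(scores, fraction = config$top_fraction)
      writeLines(top$gene, file.path(out, "top_reversed_genes.txt"))
      write_gmt(list(top_reversed = top$gene),
                file.path(out, "top_reversed_genes.gmt"))
      gene_stage <- list(category = sel$category, label = sel$label,
                        n_genes_scored = nrow(scores),
                        n_top = nrow(top))
    }
  }

  manifest <- list(
    input_checksums = as.list(tools::md5sum(inputs)),
    n_input_signatures = nrow(signatures),
    exclusions = as.list(report$exclusions),
    n_retained_signatures = nrow(pruned),
    n_unique_pairs = nrow(pairs),
    n_indicated = nrow(groups$indicated),
    n_control = nrow(groups$control),
    overall_t_test = overall,
    n_subgroups = nrow(results),
    n_tested_subgroups = sum(results$tested),
    n_significant = sum(results$q_value < config$fdr_threshold,
                        na.rm = TRUE),
    gene_reversal = gene_stage
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
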