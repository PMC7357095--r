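#' Per-gene direction agreement between two signatures
#'
#' For each gene appearing in either signature: `same` when the gene is
#' up in both or down in both, `reverse` when it is up in one and down in
#' the other, `absent` when it appears in only one of the two signatures.
#'
#' @param drug_sig,disease_sig One-row signature tibbles (or lists with
#'   `up_genes` / `down_genes`).
#' @param gene_universe Optional character vector; when given, the result
#'   covers exactly these genes (genes in neither signature are `absent`).
#' @return Tibble `gene`, `direction`.
#' @export
count_directions <- function(drug_sig, disease_sig, gene_universe = NULL) {
  a <- signature_sets(drug_sig)
  b <- signature_sets(disease_sig)
  genes <- gene_universe %||% sort(unique(c(a$up, a$down, b$up, b$down)))
  da <- direction_of(genes, a)
  db <- direction_of(genes, b)
  direction <- rep("absent", length(genes))
  direction[da != 0L & da == db] <- "same"
  direction[da != 0L & db != 0L & da != db] <- "reverse"
  tibble(gene = genes, direction = direction)
}

# +1 up, -1 down, 0 absent
direction_of <- function(genes, sets) {
  d <- integer(length(genes))
  d[genes %in% sets$up] <- 1L
  d[genes %in% sets$down] <- -1L
  d
}

#' Per-gene relative reversal scores G^I-R%
#'
#' For every gene, counts over each group of signature-level (assay-level)
#' drug-disease pairs how often the gene shows the same (`NS`) or reverse
#' (`NR`) regulation direction, computes
#' \deqn{D\% = 100 (NS - NR) / \textrm{total pairs}}
#' per group, and scores the gene with the indicated-minus-random
#' difference \eqn{G^{I-R}\% = D^I\% - D^R\%}. Strongly negative scores
#' mark genes reversed between drug and disease specifically in indicated
#' pairs. By the formulas the score can range over \[-200, 200\] (each D%
#' is bounded by +/-100).
#'
#' @param signatures Validated signature tibble covering all referenced
#'   ids.
#' @param indicated_pairs,random_pairs Tibbles (or data frames) with
#'   columns `drug_signature_id`, `disease_signature_id`; both non-empty.
#' @param gene_universe Optional character vector; defaults to all genes
#'   appearing in any signature involved in either group.
#' @param denominator `"all_pairs"` (default; pairs where the gene is
#'   absent count in the denominator only, as the D% formula states) or
#'   `"present_pairs"` (per-gene denominator `NS + NR`, for sensitivity
#'   analysis).
#' @return Tibble `gene`, `ns_indicated`, `nr_indicated`, `d_indicated`,
#'   `ns_random`, `nr_random`, `d_random`, `g_ir`, sorted by `g_ir`
#'   ascending (most reversed first) with lexicographic gene tie-break.
#' @export
g_ir_scores <- function(signatures, indicated_pairs, random_pairs,
                        gene_universe = NULL,
                        denominator = c("all_pairs", "present_pairs")) {
  denominator <- match.arg(denominator)
  if (nrow(indicated_pairs) == 0L) abort("indicated pair group is empty")
  if (nrow(random_pairs) == 0L) abort("random pair group is empty")

  ids <- unique(c(indicated_pairs$drug_signature_id,
                  indicated_pairs$disease_signature_id,
                  random_pairs$drug_signature_id,
                  random_pairs$disease_signature_id))
  miss <- setdiff(ids, signatures$signature_id)
  if (length(miss)) {
    abort(paste0("unknown signature ids: ", paste(head(miss, 5),
                 collapse = ", ")))
  }
  sigs <- signatures[match(ids, signatures$signature_id), ]
  universe <- gene_universe %||%
    sort(unique(c(unlist(sigs$up_genes), unlist(sigs$down_genes))))

  # direction matrix: genes x signatures, entries -1/0/+1
  dirmat <- vapply(seq_len(nrow(sigs)), function(j) {
    direction_of(universe, list(up = sigs$up_genes[[j]],
                                down = sigs$down_genes[[j]]))
  }, integer(length(universe)))
  if (is.null(dim(dirmat))) dirmat <- matrix(dirmat, nrow = length(universe))
  colnames(dirmat) <- sigs$signature_id

  tally <- function(pairs) {
    ns <- integer(length(universe)); nr <- integer(length(universe))
    for (k in seq_len(nrow(pairs))) {
      prod <- dirmat[, pairs$drug_signature_id[k]] *
        dirmat[, pairs$disease_signature_id[k]]
      ns <- ns + (prod == 1L)
      nr <- nr + (prod == -1L)
    }
    list(ns = ns, nr = nr, total = nrow(pairs))
  }
  ti <- tally(indicated_pairs)
  tr <- tally(random_pairs)

  dpct <- function(t) {
    if (denominator == "all_pairs") {
      100 * (t$ns - t$nr) / t$total
    } else {
      den <- t$ns + t$nr
      ifelse(den == 0L, 0, 100 * (t$ns - t$nr) / den)
    }
  }
  out <- tibble(
    gene = universe,
    ns_indicated = ti$ns, nr_indicated = ti$nr, d_indicated = dpct(ti),
    ns_random = tr$ns, nr_random = tr$nr, d_random = dpct(tr),
  )
  out$g_ir <- out$d_indicated - out$d_random
  out[order(out$g_ir, out$gene), , drop = FALSE]
}

#' Select the most reversed genes
#'
#' Ranks genes ascending by `g_ir` (most negative first, i.e. most
#' reversed) and returns the top `floor(n * fraction)` genes, or an
#' explicit `count`. Ties at the cutoff are broken by lexicographic gene
#' symbol order, so selection is deterministic.
#'
#' @param scores Output of [g_ir_scores()].
#' @param fraction Fraction in (0, 1\]; exactly one of `fraction` / `count`.
#' @param count Explicit number of genes.
#' @return Tibble of the selected rows, ranked.
#' @export
select_top_reversed <- function(scores, fraction = NULL, count = NULL) {
  if (is.null(fraction) == is.null(count)) {
    abort("give exactly one of fraction or count")
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
    count <- floor(nrow(scores) * fraction)
  }
  count <- min(as.integer(count), nrow(scores))
  ranked <- scores[order(scores$g_ir, scores$gene), , drop = FALSE]
  ranked[seq_len(count), , drop = FALSE]
}

#' Assay-level pair groups for one subgroup
#'
#' Builds the two signature-level pair groups the gene reversal score is
#' computed over: all signature pairs behind the indicated unique pairs
#' carrying the chosen subgroup label, versus all signature pairs behind
#' control (non-indicated) unique pairs involving that subgroup's drugs.
#'
#' @param pairs Unique-pair tibble.
#' @param subgroup_table Output of [build_subgroup_table()].
#' @param signatures Signature tibble.
#' @param category,label Subgroup selector.
#' @return List of tibbles `indicated`, `random`, each with
#'   `drug_signature_id`, `disease_signature_id`.
#' @export
reversal_input_pairs <- function(pairs, subgroup_table, signatures,
                                 category, label) {
  sel <- subgroup_table[subgroup_table$category == category &
                          subgroup_table$subgroup_label == label, ,
                        drop = FALSE]
  tagged <- inner_join(pairs, sel[, c("drug", "disease")],
                       by = c("drug", "disease"))
  ind_pairs <- tagged[tagged$indicated, , drop = FALSE]
  if (nrow(ind_pairs) == 0L) {
    abort(paste0("subgroup ", label, " has no indicated pairs"))
  }
  sub_drugs <- unique(ind_pairs$drug)
  ctl_pairs <- pairs[!pairs$indicated & pairs$drug %in% sub_drugs, ,
                     drop = FALSE]
  expand <- function(p) {
    bind_rows(lapply(seq_len(nrow(p)), function(i) {
      ds <- signatures$signature_id[
        signatures$entity_kind == "drug" &
          signatures$entity_name == p$drug[i]]
      zs <- signatures$signature_id[
        signatures$entity_kind == "disease" &
          signatures$entity_name == p$disease[i]]
      tidyr::expand_grid(drug_signature_id = ds, disease_signature_id = zs)
    }))
  }
  list(indicated = expand(ind_pairs), random = expand(ctl_pairs))
}

#' Write gene reversal scores as TSV
#'
#' @param scores Output of [g_ir_scores()].
#' @param path Output path.
#' @export
write_gene_scores <- function(scores, path) {
  write_tsv_file(scores, path)
}
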