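# random signature over a small universe; up/down disjoint by construction
random_signature <- function(id, universe, max_per_side = 8L,
                             kind = "drug") {
  n_up <- sample(0:max_per_side, 1)
  n_dn <- sample(0:max_per_side, 1)
  if (n_up + n_dn == 0L) n_up <- 1L
  g <- sample(universe, min(n_up + n_dn, length(universe)))
  up <- g[seq_len(min(n_up, length(g)))]
  ges_signature(id, up_genes = up, down_genes = setdiff(g, up),
                entity_kind = kind)
}

# brute-force SJI: enumerate every gene's membership pattern across the
# four direction sets, accumulate intersection/union counts per component
oracle_sji <- function(up1, dn1, up2, dn2) {
  genes <- unique(c(up1, dn1, up2, dn2))
  memb <- cbind(genes %in% up1, genes %in% dn1,
                genes %in% up2, genes %in% dn2)
  j <- function(a, b) {
    inter <- sum(memb[, a] & memb[, b])
    uni <- sum(memb[, a] | memb[, b])
    if (uni == 0L) 0 else inter / uni
  }
  ((j(1, 3) + j(2, 4)) - (j(1, 4) + j(2, 3))) / 2
}

# one single-gene pair per row: direction "s" same, "r" reverse, "a" absent;
# used to construct NS/NR counting cases for the gene reversal score
pairs_for_gene <- function(dirs, gene = "TP53", prefix = "p") {
  sigs <- list(); keys <- list()
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    drug_id <- sprintf("%s_drug%02d", prefix, i)
    dz_id <- sprintf("%s_dz%02d", prefix, i)
    filler <- sprintf("FILL%s%02d", prefix, i)
    drug_up <- if (d == "a") filler else gene
    dz_up <- if (d == "r") character() else gene
    dz_dn <- if (d == "r") gene else character()
    sigs[[length(sigs) + 1L]] <-
      ges_signature(drug_id, drug_up, character(), entity_kind = "drug")
    sigs[[length(sigs) + 1L]] <-
      ges_signature(dz_id, c(dz_up, filler), dz_dn, entity_kind = "disease")
    keys[[i]] <- tibble::tibble(drug_signature_id = drug_id,
                                disease_signature_id = dz_id)
  }
  list(signatures = validate_signatures(dplyr::bind_rows(sigs)),
       pairs = dplyr::bind_rows(keys))
}

# hand-written BH step-up, independent of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# run the standard analysis chain on a synthetic study
analyze_study <- function(study, fdr_family = "pooled") {
  drugs <- study$signatures[study$signatures$entity_kind == "drug", ]
  dz <- study$signatures[study$signatures$entity_kind == "disease", ]
  sji <- pairwise_sji_matrix(drugs, dz)
  pairs <- build_unique_pairs(sji, study$signatures, study$indications)
  sub <- suppressMessages(build_subgroup_table(pairs, study$annotations))
  list(pairs = pairs, subgroups = sub,
       results = subgroup_analysis(pairs, sub, fdr_family = fdr_family))
}
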