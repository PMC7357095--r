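#' Jaccard similarity coefficient between two gene sets
#'
#' `SAME / ALL`, where `SAME` is the number of genes shared by the two sets
#' and `ALL` the number of unique genes appearing in either. When both sets
#' are empty the coefficient is 0 by convention (the quotient is undefined;
#' an empty signature direction carries no evidence of similarity).
#'
#' @param set_a,set_b Character vectors of gene symbols (normalized
#'   internally).
#' @return A `ges_jaccard` list: `value`, `same_count`, `all_count`.
#' @examples
#' jaccard(c("A", "B"), c("B", "C"))$value  # 1/3
#' @export
jaccard <- function(set_a, set_b) {
  a <- normalize_gene_symbols(set_a)
  b <- normalize_gene_symbols(set_b)
  same <- length(intersect(a, b))
  all_ <- length(a) + length(b) - same
  structure(
    list(value = if (all_ == 0L) 0 else same / all_,
         same_count = same, all_count = all_),
    class = "ges_jaccard"
  )
}

#' Signed Jaccard index between two signatures
#'
#' Combines the Jaccard coefficient with regulation direction:
#' \deqn{SJI = (J(up_1, up_2) + J(down_1, down_2) - J(up_1, down_2) -
#'   J(down_1, up_2)) / 2}
#' ranging from +1 (identical pattern) to -1 (perfectly inverse pattern);
#' 0 means no association, or same- and cross-direction overlap cancelling
#' out. The four component terms are retained for audit.
#'
#' @param sig1,sig2 One-row signature tibbles (or lists with `up_genes` /
#'   `down_genes` elements). Each signature must have disjoint up/down sets.
#' @return A `ges_sji` list: `value`, `j_uu`, `j_dd`, `j_ud`, `j_du`.
#' @export
signed_jaccard <- function(sig1, sig2) {
  s1 <- signature_sets(sig1)
  s2 <- signature_sets(sig2)
  for (s in list(s1, s2)) {
    if (length(intersect(s$up, s$down)) > 0L) {
      abort("signature has overlapping up and down sets; validate first")
    }
  }
  j_uu <- jaccard(s1$up, s2$up)$value
  j_dd <- jaccard(s1$down, s2$down)$value
  j_ud <- jaccard(s1$up, s2$down)$value
  j_du <- jaccard(s1$down, s2$up)$value
  # same-terms and cross-terms grouped before subtracting, so argument
  # order (symmetry) and direction swap (antisymmetry) are bit-exact
  structure(
    list(value = ((j_uu + j_dd) - (j_ud + j_du)) / 2,
         j_uu = j_uu, j_dd = j_dd, j_ud = j_ud, j_du = j_du),
    class = "ges_sji"
  )
}

signature_sets <- function(sig) {
  if (is.data.frame(sig)) {
    stopifnot(nrow(sig) == 1L)
    list(up = sig$up_genes[[1]], down = sig$down_genes[[1]])
  } else {
    list(up = sig$up_genes, down = sig$down_genes)
  }
}

#' @export
print.ges_sji <- function(x, ...) {
  cat(sprintf(
    "SJI = %.4f  (J_uu=%.4f J_dd=%.4f J_ud=%.4f J_du=%.4f)\n",
    x$value, x$j_uu, x$j_dd, x$j_ud, x$j_du))
  invisible(x)
}

#' Signed Jaccard index for all drug x disease signature pairs
#'
#' Scores every combination of one drug signature and one disease
#' signature. Internally the gene universe is mapped to a gene-by-signature
#' incidence matrix per direction and the four intersection-count matrices
#' are obtained by cross-products, which is exactly equivalent to calling
#' [signed_jaccard()] pair by pair (asserted in the test suite) but scales
#' to thousands of pairs.
#'
#' @param drugs,diseases Validated signature tibbles (non-empty).
#' @return Tibble with one row per pair, ordered lexicographically by drug
#'   then disease signature id: columns `drug_signature_id`,
#'   `disease_signature_id`, `sji`, `j_uu`, `j_dd`, `j_ud`, `j_du`.
#' @export
pairwise_sji_matrix <- function(drugs, diseases) {
  if (nrow(drugs) == 0L || nrow(diseases) == 0L) {
    abort("both signature collections must be non-empty")
  }
  drugs <- drugs[order(drugs$signature_id), , drop = FALSE]
  diseases <- diseases[order(diseases$signature_id), , drop = FALSE]
  universe <- unique(c(unlist(drugs$up_genes), unlist(drugs$down_genes),
                       unlist(diseases$up_genes),
                       unlist(diseases$down_genes)))

  incidence <- function(sets) {
    m <- matrix(0, nrow = length(universe), ncol = length(sets))
    for (j in seq_along(sets)) {
      m[match(sets[[j]], universe), j] <- 1
    }
    m
  }
  u1 <- incidence(drugs$up_genes);    d1 <- incidence(drugs$down_genes)
  u2 <- incidence(diseases$up_genes); d2 <- incidence(diseases$down_genes)

  jac <- function(a, b) {
    inter <- crossprod(a, b)
    union <- outer(colSums(a), colSums(b), `+`) - inter
    out <- inter / union
    out[union == 0] <- 0
    out
  }
  j_uu <- jac(u1, u2); j_dd <- jac(d1, d2)
  j_ud <- jac(u1, d2); j_du <- jac(d1, u2)
  sji <- ((j_uu + j_dd) - (j_ud + j_du)) / 2

  nd <- nrow(drugs); nz <- nrow(diseases)
  tibble(
    drug_signature_id = rep(drugs$signature_id, each = nz),
    disease_signature_id = rep(diseases$signature_id, times = nd),
    sji = as.vector(t(sji)),
    j_uu = as.vector(t(j_uu)), j_dd = as.vector(t(j_dd)),
    j_ud = as.vector(t(j_ud)), j_du = as.vector(t(j_du))
  )
}

#' Write an SJI pair table as TSV
#'
#' @param sji_table Output of [pairwise_sji_matrix()].
#' @param path Output path.
#' @export
write_sji_matrix <- function(sji_table, path) {
  write_tsv_file(sji_table, path)
}
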