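two_sided_sigs <- function() {
  validate_signatures(dplyr::bind_rows(
    ges_signature("drug:1", "A", "B", entity_name = "cocaine"),
    ges_signature("drug:2", "C", "D", entity_name = "prednisone"),
    ges_signature("dz:1", "E", "F", entity_name = "asthma",
                  entity_kind = "disease")
  ))
}

test_that("unpaired drugs and diseases are pruned to a fixed point", {
  sigs <- two_sided_sigs()
  ind <- indication_table(c("cocaine", "prednisone"),
                          c("local anesthesia", "asthma"))
  pruned <- prune_unpaired(sigs, ind)
  expect_equal(sort(pruned$signature_id), c("drug:2", "dz:1"))
  expect_equal(attr(pruned, "n_pruned"), 1L)

  # chain case: disease kept only via drug A; removing drug A (not in the
  # collection) orphans the disease at the fixed point
  sigs2 <- validate_signatures(dplyr::bind_rows(
    ges_signature("drug:2", "C", "D", entity_name = "prednisone"),
    ges_signature("dz:1", "E", "F", entity_name = "asthma",
                  entity_kind = "disease"),
    ges_signature("dz:2", "G", "H", entity_name = "lupus",
                  entity_kind = "disease")
  ))
  ind2 <- indication_table(c("prednisone", "removeddrug"),
                           c("asthma", "lupus"))
  pruned2 <- prune_unpaired(sigs2, ind2)
  expect_false("dz:2" %in% pruned2$signature_id)

  expect_error(
    prune_unpaired(sigs, indication_table("cocaine", "local anesthesia")),
    "no analyzable pairs")
})

test_that("unique pairs average all signature-level SJIs", {
  # drug with 2 signatures x disease with 3 signatures
  sji <- tibble::tibble(
    drug_signature_id = rep(c("drug:1", "drug:2"), each = 3),
    disease_signature_id = rep(c("dz:1", "dz:2", "dz:3"), 2),
    sji = c(0.2, -0.4, 0.5, 0.1, -0.1, 0.3)
  )
  sigs <- validate_signatures(dplyr::bind_rows(
    ges_signature("drug:1", "A", "B", entity_name = "metformin"),
    ges_signature("drug:2", "C", "D", entity_name = "metformin"),
    ges_signature("dz:1", "E", "F", entity_name = "diabetes",
                  entity_kind = "disease"),
    ges_signature("dz:2", "G", "H", entity_name = "diabetes",
                  entity_kind = "disease"),
    ges_signature("dz:3", "I", "J", entity_name = "diabetes",
                  entity_kind = "disease")
  ))
  pairs <- build_unique_pairs(sji, sigs,
                              indication_table("metformin", "diabetes"))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$n_signature_pairs, 6L)
  expect_equal(pairs$mean_sji, 0.1)
  expect_true(pairs$indicated)

  # permuting signature-pair order never changes the mean
  perm <- sji[sample(6), ]
  expect_equal(build_unique_pairs(perm, sigs,
                                  indication_table("metformin",
                                                   "diabetes"))$mean_sji,
               0.1)
})

test_that("full crossing yields drugs x diseases unique pairs", {
  set.seed(3)
  universe <- paste0("G", 1:60)
  sigs <- validate_signatures(dplyr::bind_rows(
    lapply(1:4, function(i) {
      s <- random_signature(sprintf("drug:%d", i), universe)
      s$entity_name <- sprintf("drug %d", (i - 1) %/% 2 + 1)  # 2 drugs
      s
    }),
    lapply(1:3, function(i) {
      s <- random_signature(sprintf("dz:%d", i), universe, kind = "disease")
      s$entity_name <- sprintf("disease %d", i)
      s
    })
  ))
  m <- pairwise_sji_matrix(sigs[sigs$entity_kind == "drug", ],
                           sigs[sigs$entity_kind == "disease", ])
  pairs <- build_unique_pairs(m, sigs,
                              indication_table("drug 1", "disease 1"))
  expect_equal(nrow(pairs), 2L * 3L)
  expect_equal(sum(pairs$indicated), 1L)
})

test_that("indication split partitions the pair table", {
  pairs <- tibble::tibble(
    drug = paste0("d", 1:10), disease = paste0("z", 1:10),
    n_signature_pairs = 1L, sji_values = as.list(rnorm(10)),
    mean_sji = rnorm(10),
    indicated = c(rep(TRUE, 3), rep(FALSE, 7))
  )
  g <- split_by_indication(pairs)
  expect_equal(nrow(g$indicated), 3L)
  expect_equal(nrow(g$control), 7L)
  expect_equal(nrow(g$indicated) + nrow(g$control), nrow(pairs))

  pairs$indicated <- FALSE
  expect_error(split_by_indication(pairs), "no indicated")
  pairs$indicated <- TRUE
  expect_warning(split_by_indication(pairs), "control group is empty")
})
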