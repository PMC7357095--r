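make_filter_input <- function() {
  validate_signatures(dplyr::bind_rows(
    ges_signature("drug:2772", "A", "B", entity_name = "alefacept",
                  series_id = "GSE10432"),
    ges_signature("dz:297", "C", "D", entity_name = "wrong disease",
                  series_id = "GSE10432"),
    ges_signature("drug:2485", "E", "F", entity_name = "salbutamol",
                  series_id = "GSE31773"),
    ges_signature("dz:712", "G", "H", entity_name = "asthma",
                  series_id = "GSE31773"),
    ges_signature("dz:713", "I", "J", entity_name = "asthma",
                  series_id = "GSE31773"),
    ges_signature("drug:3288", "K", "L", entity_name = "mousedrug",
                  series_id = "GSE7762", organism = "Mus musculus"),
    ges_signature("drug:9999", "M", "N", entity_name = "unapproved thing",
                  series_id = "GSE9999")
  ))
}

test_that("inclusion filters remove in order and account for every signature", {
  sigs <- make_filter_input()
  cfg <- filter_config(
    approved_drugs = c("alefacept", "salbutamol", "mousedrug"),
    excluded_ids = "dz:297"
  )
  out <- apply_inclusion_filters(sigs, cfg)
  r <- out$report
  expect_equal(unname(r$exclusions[["non_human"]]), 1L)      # mouse drug
  expect_equal(unname(r$exclusions[["not_approved"]]), 1L)
  expect_equal(unname(r$exclusions[["mis_specified"]]), 1L)  # dz:297
  expect_equal(unname(r$exclusions[["dual_label"]]), 1L)     # drug:2485
  # conservation: input = retained + sum(excluded)
  expect_equal(r$n_input,
               r$retained_drugs + r$retained_diseases + sum(r$exclusions))
  # dz:297 is handled by the exclusion list, so the GSE10432 drug survives
  expect_true("drug:2772" %in% out$signatures$signature_id)
  expect_false("dz:297" %in% out$signatures$signature_id)
  # GSE31773 keeps all its disease signatures, drops the drug side
  expect_true(all(c("dz:712", "dz:713") %in% out$signatures$signature_id))
  expect_false("drug:2485" %in% out$signatures$signature_id)
})

test_that("filtering is idempotent and identity on a clean collection", {
  sigs <- make_filter_input()
  cfg <- filter_config(
    approved_drugs = c("alefacept", "salbutamol", "mousedrug"),
    excluded_ids = "dz:297"
  )
  once <- apply_inclusion_filters(sigs, cfg)
  twice <- apply_inclusion_filters(once$signatures, cfg)
  expect_equal(twice$signatures, once$signatures)
  expect_equal(sum(twice$report$exclusions), 0L)

  clean <- validate_signatures(dplyr::bind_rows(
    ges_signature("drug:1", "A", "B", entity_name = "aspirin"),
    ges_signature("dz:1", "C", "D", entity_name = "fever")
  ))
  out <- apply_inclusion_filters(clean, filter_config("aspirin"))
  expect_equal(nrow(out$signatures), 2L)
  expect_equal(sum(out$report$exclusions), 0L)
})

test_that("organism matching is case-insensitive through the synonym table", {
  sigs <- validate_signatures(dplyr::bind_rows(
    ges_signature("dz:1", "A", "B", entity_name = "x",
                  organism = "Homo sapiens"),
    ges_signature("dz:2", "C", "D", entity_name = "y", organism = "HUMAN"),
    ges_signature("dz:3", "E", "F", entity_name = "z", organism = "mouse")
  ))
  out <- apply_inclusion_filters(sigs, filter_config(character()))
  expect_equal(sort(out$signatures$signature_id), c("dz:1", "dz:2"))
})

test_that("dual-label policies resolve multi-signature series as configured", {
  sigs <- validate_signatures(dplyr::bind_rows(
    ges_signature("drug:3289", "A", "B", entity_name = "mesalazine",
                  series_id = "GSE38713"),
    ges_signature("drug:3194", "C", "D", entity_name = "mesalazine",
                  series_id = "GSE38713"),
    ges_signature("drug:3195", "E", "F", entity_name = "mesalazine",
                  series_id = "GSE38713"),
    ges_signature("dz:810", "G", "H", entity_name = "ulcerative colitis",
                  series_id = "GSE38713"),
    ges_signature("dz:1", "I", "J", entity_name = "other",
                  series_id = "GSE1")
  ))
  kept <- resolve_dual_labels(sigs, "keep_disease")
  expect_equal(sort(kept$signature_id), c("dz:1", "dz:810"))
  kept_drug <- resolve_dual_labels(sigs, "keep_drug")
  expect_false("dz:810" %in% kept_drug$signature_id)
  expect_true("dz:1" %in% kept_drug$signature_id)  # single-kind series kept
  none <- resolve_dual_labels(sigs, "drop_both")
  expect_equal(none$signature_id, "dz:1")
})
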