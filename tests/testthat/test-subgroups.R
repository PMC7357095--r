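toy_bundle <- function() {
  annotation_bundle(
    drug_targets = tibble::tibble(
      drug = c("dexamethasone", "doxycycline", "imatinib", "paclitaxel",
               "methotrexate", "methotrexate"),
      target = c("glucocorticoid receptor", "16S ribosomal RNA",
                 "tyrosine kinase", "micro-tubules",
                 "nucleotide synthesis", "Beta-1 adrenergic receptor")
    ),
    icd11_level1 = tibble::tibble(
      disease = c("asthma", "leukemia"),
      disease_class = c("diseases of the respiratory system", "neoplasms")
    ),
    atc3 = tibble::tibble(
      drug = c("dexamethasone", "doxycycline", "imatinib", "paclitaxel",
               "methotrexate"),
      atc3 = c("H02 corticosteroids topical", "J01 tetracyclines",
               "L01 protein kinase inhibitors", "L01 plant alkaloids",
               "L04 immunosuppressants")
    ),
    target_grouping = tibble::tibble(
      target = c("Beta-1 adrenergic receptor", "Beta-2 adrenergic receptor"),
      group = "Beta adrenergic receptors"
    ),
    tf_targets = "glucocorticoid receptor",
    nonhuman_targets = "16S ribosomal RNA",
    atc_unification = tibble::tibble(
      atc3 = "H02 corticosteroids topical",
      unified = "H02 corticosteroids for systemic use"
    )
  )
}

test_that("TF level is directly / non_human / not_directly by target sets", {
  b <- toy_bundle()
  tf <- assign_tf_level(b$drug_targets, b$tf_targets, b$nonhuman_targets)
  lv <- setNames(tf$tf_level, tf$drug)
  expect_equal(unname(lv["dexamethasone"]), "directly")
  expect_equal(unname(lv["doxycycline"]), "non_human")
  expect_equal(unname(lv["imatinib"]), "not_directly")
  expect_equal(unname(lv["methotrexate"]), "not_directly")
})

test_that("chemotherapy status follows target classes and can be dual", {
  b <- toy_bundle()
  ch <- assign_chemotherapy(b$drug_targets)
  get <- function(d) sort(ch$chemo_label[ch$drug == d])
  expect_equal(get("paclitaxel"), "chemo")          # micro-tubules
  expect_equal(get("imatinib"), "non_chemo")
  expect_equal(get("methotrexate"), c("chemo", "non_chemo"))
})

test_that("subgroup table applies grouping, unification, and partitions", {
  b <- toy_bundle()
  pairs <- tibble::tibble(
    drug = c("dexamethasone", "methotrexate", "paclitaxel"),
    disease = c("asthma", "leukemia", "leukemia"),
    n_signature_pairs = 1L, sji_values = list(0, 0, 0),
    mean_sji = c(-0.1, -0.2, 0.05),
    indicated = c(TRUE, TRUE, FALSE)
  )
  tab <- suppressMessages(build_subgroup_table(pairs, b))

  # raw beta-receptor target is reported under its grouped subfamily
  tgt <- tab[tab$category == "target" & tab$drug == "methotrexate", ]
  expect_setequal(tgt$subgroup_label,
                  c("nucleotide synthesis", "Beta adrenergic receptors"))

  # route-specific ATC code unified to systemic use
  atc <- tab[tab$category == "atc" & tab$drug == "dexamethasone", ]
  expect_equal(atc$subgroup_label, "H02 corticosteroids for systemic use")

  # tf_level and disease_class are partitions: exactly one label per pair
  for (cat in c("tf_level", "disease_class")) {
    per_pair <- table(paste(tab$drug[tab$category == cat],
                            tab$disease[tab$category == cat]))
    expect_true(all(per_pair == 1L))
  }

  # chemotherapy multi-labels the dual-status drug
  ch <- tab[tab$category == "chemotherapy" & tab$drug == "methotrexate", ]
  expect_setequal(ch$subgroup_label, c("chemo", "non_chemo"))

  # deterministic and order-independent
  tab2 <- suppressMessages(build_subgroup_table(pairs[c(3, 1, 2), ], b))
  expect_equal(tab, tab2)
})

test_that("pairs unannotated in a category are omitted from it only", {
  b <- toy_bundle()
  pairs <- tibble::tibble(
    drug = c("dexamethasone", "mysterydrug"),
    disease = c("asthma", "asthma"),
    n_signature_pairs = 1L, sji_values = list(0, 0),
    mean_sji = c(-0.1, 0), indicated = c(TRUE, FALSE)
  )
  expect_message(tab <- build_subgroup_table(pairs, b), "unannotated")
  expect_false("mysterydrug" %in% tab$drug[tab$category == "target"])
  expect_true("mysterydrug" %in% tab$drug[tab$category == "disease_class"])
})
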