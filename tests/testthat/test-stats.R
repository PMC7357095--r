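test_that("overall t-test matches hand-computed pooled statistics", {
  r <- overall_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- overall_t_test(c(-0.2, -0.1, 0), c(0, 0.1, 0.2), variant = "pooled")
  expect_equal(r$t, -0.2 / sqrt(0.01 * (2 / 3)), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(r$t, 4), tolerance = 1e-10)

  expect_error(overall_t_test(0.5, c(1, 2)), "at least 2")
  expect_error(overall_t_test(c(1, 1), c(2, 2)), "degenerate")
})

make_pairs <- function(subgroup, indicated, y) {
  list(
    pairs = tibble::tibble(
      drug = paste0("d", seq_along(y)), disease = paste0("z", seq_along(y)),
      mean_sji = y, indicated = indicated
    ),
    subgroups = tibble::tibble(
      drug = paste0("d", seq_along(y)), disease = paste0("z", seq_along(y)),
      category = "disease_class", subgroup_label = subgroup
    )
  )
}

test_that("slice F test reproduces the hand-worked two-subgroup design", {
  d <- make_pairs(
    subgroup = c("A", "A", "A", "A", "B", "B", "B"),
    indicated = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    y = c(-0.2, -0.1, 0.1, 0.2, 0, 0.05, -0.05)
  )
  res <- slice_f_tests(d$pairs, d$subgroups, "disease_class")
  a <- res[res$subgroup_label == "A", ]
  expect_equal(a$mse, 0.005)
  expect_equal(a$f_statistic, 18)
  expect_equal(a$df2, 3L)
  expect_equal(a$p_value, pf(18, 1, 3, lower.tail = FALSE))
  # single indicated pair is testable; its SD is undefined
  b <- res[res$subgroup_label == "B", ]
  expect_true(b$tested)
  expect_true(is.na(b$sd_indicated))
  expect_equal(b$f_statistic, 0)
  expect_equal(b$p_value, 1)
})

test_that("subgroups with one indication level are untested; df errors raised", {
  d <- make_pairs(
    subgroup = c("A", "A", "A", "A", "C", "C"),
    indicated = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    y = c(-0.2, -0.1, 0.1, 0.2, 0.3, 0.1)
  )
  res <- slice_f_tests(d$pairs, d$subgroups, "disease_class")
  expect_false(res$tested[res$subgroup_label == "C"])
  expect_true(is.na(res$p_value[res$subgroup_label == "C"]))

  sat <- make_pairs("A", c(TRUE, FALSE), c(0.1, 0.2))
  expect_error(slice_f_tests(sat$pairs, sat$subgroups, "disease_class"),
               "degrees of freedom")
})

test_that("slice F agrees with an lm + emmeans least-squares oracle", {
  skip_if_not_installed("emmeans")
  set.seed(99)
  n <- 60
  sub <- sample(c("A", "B", "C"), n, replace = TRUE)
  ind <- stats::runif(n) < 0.3
  # ensure both levels in every subgroup
  ind[match(c("A", "B", "C"), sub)] <- TRUE
  ind[n - match(c("A", "B", "C"), rev(sub)) + 1] <- FALSE
  y <- rnorm(n, sd = 0.05) - 0.1 * (sub == "B" & ind)
  d <- make_pairs(sub, ind, y)
  res <- slice_f_tests(d$pairs, d$subgroups, "disease_class")

  df <- data.frame(y = y, sub = sub, ind = factor(ind))
  fit <- stats::lm(y ~ sub * ind, data = df)
  emm <- emmeans::emmeans(fit, ~ ind | sub)
  ora <- as.data.frame(emmeans::test(emmeans::contrast(emm, "pairwise")))
  for (s in c("A", "B", "C")) {
    f_pkg <- res$f_statistic[res$subgroup_label == s]
    t_ora <- ora$t.ratio[ora$sub == s]
    expect_equal(f_pkg, t_ora^2, tolerance = 1e-8)
    expect_equal(res$p_value[res$subgroup_label == s],
                 ora$p.value[ora$sub == s], tolerance = 1e-8)
    expect_equal(res$df2[res$subgroup_label == s], ora$df[ora$sub == s])
  }
})

test_that("BH q-values match the step-up oracle and are permutation-stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("pooled FDR family spans categories; per-category family is local", {
  set.seed(8)
  study <- generate_study(simulation_config(seed = 31, n_drugs = 10,
                                            n_diseases = 12))
  a <- analyze_study(study, fdr_family = "pooled")
  r <- a$results
  expect_equal(r$q_value[r$tested],
               oracle_bh(r$p_value[r$tested]), tolerance = 1e-12)
  b <- analyze_study(study, fdr_family = "per_category")$results
  for (cat in unique(b$category)) {
    idx <- b$tested & b$category == cat
    expect_equal(b$q_value[idx], oracle_bh(b$p_value[idx]),
                 tolerance = 1e-12)
  }
})

test_that("subgroup results render undefined SDs as dashes in TSV", {
  d <- make_pairs(
    subgroup = c("A", "A", "A", "B", "B", "B"),
    indicated = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    y = c(-0.1, 0.1, 0.2, 0, 0.1, -0.05)
  )
  res <- subgroup_analysis(d$pairs, d$subgroups)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subgroup_results(res, path)
  out <- read.delim(path)
  expect_true("----------" %in% out$sd_indicated)
})
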