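#' Two-sided t-test of indicated vs control mean SJI
#'
#' Compares the mean signed Jaccard index of indicated unique pairs with
#' that of the random control group. The pooled-variance variant is the
#' default, consistent with the equal-variance assumption of the subgroup
#' linear model; Welch is available by flag.
#'
#' @param indicated_sjis,control_sjis Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List `t`, `df`, `p`, `variant`, plus group means/sds/sizes.
#' @export
overall_t_test <- function(indicated_sjis, control_sjis,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as.numeric(indicated_sjis); y <- as.numeric(control_sjis)
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least 2 values for a t-test")
  }
  base <- list(variant = variant,
               n_indicated = length(x), n_control = length(y),
               mean_indicated = mean(x), sd_indicated = sd(x),
               mean_control = mean(y), sd_control = sd(y))
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(c(list(t = 0, df = length(x) + length(y) - 2, p = 1), base))
    }
    abort("degenerate input: zero variance in both groups, unequal means")
  }
  fit <- t.test(x, y, var.equal = (variant == "pooled"))
  c(list(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value), base)
}

#' Per-subgroup LS-means slice F tests within one category
#'
#' Fits a cell-means linear model of the unique-pair SJI on the cells of
#' `subgroup x indication` within a single classification category, then
#' tests the indicated-vs-control least-squares-mean difference inside each
#' subgroup with the model-wide pooled residual mean square (an unbalanced
#' design makes per-subgroup pooled t-tests inefficient; the shared MSE
#' borrows variance strength across cells):
#' \deqn{F = (\bar y_I - \bar y_C)^2 / (MSE (1/n_I + 1/n_C)),
#'   \quad df = (1, N - \#cells)}
#' Subgroups observed at only one indication level are reported untested
#' (`NA` statistics). A subgroup with a single indicated pair IS testable —
#' the pooled MSE supplies the variance — and its SD is reported as `NA`.
#'
#' Pairs may carry several labels within a multi-label category; each label
#' contributes its own cell and the model is fit on the expanded table.
#'
#' @param pairs Unique-pair tibble with `drug`, `disease`, `mean_sji`,
#'   `indicated`.
#' @param subgroup_table Output of [build_subgroup_table()].
#' @param category One of the five category names.
#' @return Tibble with one row per subgroup: sizes, means, SDs,
#'   `f_statistic`, `p_value`, `tested`. `q_value` is added by the caller
#'   (see [subgroup_analysis()]) so that the FDR family can span
#'   categories.
#' @export
slice_f_tests <- function(pairs, subgroup_table, category) {
  stopifnot(category %in% c("disease_class", "target", "tf_level",
                            "chemotherapy", "atc"))
  sub <- subgroup_table[subgroup_table$category == category, , drop = FALSE]
  if (nrow(sub) == 0L) abort(paste0("no assignments for category ", category))
  df <- inner_join(sub, pairs[, c("drug", "disease", "mean_sji",
                                  "indicated")],
                   by = c("drug", "disease"))

  cells <- df |>
    group_by(.data$subgroup_label, .data$indicated) |>
    summarise(n = n(), mean = mean(.data$mean_sji),
              var = if (n() > 1L) var(.data$mean_sji) else NA_real_,
              .groups = "drop")
  n_cells <- nrow(cells)
  n_obs <- nrow(df)
  df_resid <- n_obs - n_cells
  if (df_resid <= 0L) {
    abort("no residual degrees of freedom; merge subgroups or add pairs")
  }
  mse <- sum((cells$n - 1L) * cells$var, na.rm = TRUE) / df_resid

  wide <- tidyr::pivot_wider(
    cells,
    id_cols = "subgroup_label",
    names_from = "indicated",
    values_from = c("n", "mean", "var"),
    names_glue = "{.value}_{ifelse(indicated, 'ind', 'ctl')}"
  )
  for (col in c("n_ind", "n_ctl", "mean_ind", "mean_ctl", "var_ind",
                "var_ctl")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  tested <- !is.na(wide$n_ind) & !is.na(wide$n_ctl)
  fstat <- ifelse(
    tested,
    (wide$mean_ind - wide$mean_ctl)^2 /
      (mse * (1 / wide$n_ind + 1 / wide$n_ctl)),
    NA_real_
  )
  tibble(
    category = category,
    subgroup_label = wide$subgroup_label,
    n_indicated = as.integer(ifelse(is.na(wide$n_ind), 0L, wide$n_ind)),
    n_control = as.integer(ifelse(is.na(wide$n_ctl), 0L, wide$n_ctl)),
    mean_indicated = wide$mean_ind,
    sd_indicated = sqrt(wide$var_ind),
    mean_control = wide$mean_ctl,
    sd_control = sqrt(wide$var_ctl),
    f_statistic = fstat,
    df1 = ifelse(tested, 1L, NA_integer_),
    df2 = ifelse(tested, df_resid, NA_integer_),
    mse = mse,
    p_value = ifelse(tested, pf(fstat, 1, df_resid, lower.tail = FALSE),
                     NA_real_),
    tested = tested
  ) |>
    arrange(.data$subgroup_label)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up BH adjustment with monotone enforcement (delegates to
#' [stats::p.adjust()]). The default multiple-testing family in
#' [subgroup_analysis()] is all tested subgroups across all five
#' categories jointly.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Run the full subgroup analysis
#'
#' Applies [slice_f_tests()] to every category present in
#' `subgroup_table` (one cell-means model per category) and adjusts the
#' tested p-values with [bh_fdr()]. With `fdr_family = "pooled"` (default)
#' all tested subgroups from all categories form one BH family; with
#' `"per_category"` each category is adjusted separately.
#'
#' @param pairs Unique-pair tibble.
#' @param subgroup_table Output of [build_subgroup_table()].
#' @param fdr_family `"pooled"` or `"per_category"`.
#' @return Tibble of subgroup results with `q_value` added.
#' @export
subgroup_analysis <- function(pairs, subgroup_table,
                              fdr_family = c("pooled", "per_category")) {
  fdr_family <- match.arg(fdr_family)
  cats <- unique(subgroup_table$category)
  res <- bind_rows(lapply(cats, function(cat) {
    slice_f_tests(pairs, subgroup_table, cat)
  }))
  res$q_value <- NA_real_
  if (fdr_family == "pooled") {
    res$q_value[res$tested] <- bh_fdr(res$p_value[res$tested])
  } else {
    for (cat in cats) {
      idx <- res$tested & res$category == cat
      res$q_value[idx] <- bh_fdr(res$p_value[idx])
    }
  }
  res
}

#' Write subgroup results as TSV
#'
#' Mirrors the tabular report layout: means with SDs, group sizes and the
#' BH q-value; an undefined SD (single-pair subgroup) is rendered as
#' `"----------"`.
#'
#' @param results Output of [subgroup_analysis()].
#' @param path Output path.
#' @export
write_subgroup_results <- function(results, path) {
  fmt_sd <- function(x) ifelse(is.na(x), "----------", sprintf("%.5f", x))
  out <- tibble(
    category = results$category,
    subgroup = results$subgroup_label,
    mean_indicated = results$mean_indicated,
    sd_indicated = fmt_sd(results$sd_indicated),
    n_indicated = results$n_indicated,
    mean_control = results$mean_control,
    sd_control = fmt_sd(results$sd_control),
    n_control = results$n_control,
    f_statistic = results$f_statistic,
    p_value = results$p_value,
    q_value = results$q_value
  )
  write_tsv_file(out, path)
}
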