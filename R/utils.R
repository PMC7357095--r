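#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows n rename across
#' @importFrom stats pf pt p.adjust sd setNames t.test var
#' @importFrom utils head read.delim write.table
NULL

#' Normalize gene symbols
#'
#' Uppercases, strips surrounding whitespace, drops empty strings and
#' deduplicates. No alias mapping is attempted: symbols are matched verbatim
#' after case/whitespace normalization, so that overlap counts are not
#' silently altered by an alias dictionary.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of unique normalized symbols.
#' @export
normalize_gene_symbols <- function(x) {
  if (length(x) == 0L) return(character())
  x <- toupper(trimws(as.character(x)))
  unique(x[!is.na(x) & nzchar(x)])
}

# entity (drug/disease) names: case-insensitive, whitespace-squashed
normalize_entity_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# deterministic child seed for a named stage, kept inside 32-bit range
stage_seed <- function(seed, stage) {
  off <- sum(utf8ToInt(stage)) %% 104729L
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483587) + 1L
}

write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df[list_cols] <- lapply(df[list_cols], function(col) {
    vapply(col, function(v) paste(v, collapse = ","), character(1))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}
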