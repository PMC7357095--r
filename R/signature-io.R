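#' Read signatures from CREEDS-style JSON
#'
#' Reads an array of signature records in the CREEDS dialect: fields `id`,
#' `organism`, `geo_id` (series), `drug_name` / `disease_name`, and
#' `up_genes` / `down_genes` given either as plain symbol lists or as
#' `[symbol, weight]` pairs (the characteristic-direction weight is
#' discarded; the similarity method is unranked). Entity kind is taken from
#' an explicit `entity_kind` field when present, otherwise inferred from the
#' `drug:` / `dz:` id prefix.
#'
#' Records missing both gene lists (or an id) are skipped with a warning
#' naming the offending record; the skipped records are attached as the
#' `"problems"` attribute of the result.
#'
#' @param path Path to a JSON file.
#' @return Validated signature tibble.
#' @export
read_creeds_json <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  records <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("malformed JSON in ", path, ": ", conditionMessage(e)))
    }
  )
  if (!is.list(records)) abort("expected a JSON array of signature records")

  problems <- character()
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    id <- r$id %||% r$signature_id
    up <- extract_gene_list(r$up_genes)
    dn <- extract_gene_list(r$down_genes)
    if (is.null(id) || (length(up) == 0L && length(dn) == 0L)) {
      problems <- c(problems, paste0(
        "record ", i, " (id=", id %||% "<missing>",
        "): missing id or both gene lists"))
      next
    }
    kind <- r$entity_kind %||%
      if (startsWith(id, "dz:")) "disease" else "drug"
    name <- r$drug_name %||% r$disease_name %||% r$entity_name %||% id
    rows[[i]] <- ges_signature(
      signature_id = id,
      up_genes = up, down_genes = dn,
      entity_kind = kind, entity_name = name,
      series_id = r$geo_id %||% r$series_id %||% NA_character_,
      organism = r$organism %||% "human"
    )
  }
  if (length(problems)) {
    warn(paste0("skipped invalid records:\n  ",
                paste(problems, collapse = "\n  ")))
  }
  out <- validate_signatures(bind_rows(rows[!vapply(rows, is.null, logical(1))]))
  attr(out, "problems") <- problems
  out
}

extract_gene_list <- function(x) {
  if (is.null(x)) return(character())
  syms <- vapply(x, function(g) {
    if (is.list(g) || length(g) > 1L) as.character(g[[1]]) else as.character(g)
  }, character(1))
  normalize_gene_symbols(syms)
}

#' Write signatures as CREEDS-style JSON
#'
#' Inverse of [read_creeds_json()]; emits plain symbol lists.
#'
#' @param signatures Signature tibble.
#' @param path Output path.
#' @export
write_creeds_json <- function(signatures, path) {
  records <- lapply(seq_len(nrow(signatures)), function(i) {
    s <- signatures[i, ]
    list(
      id = s$signature_id,
      geo_id = s$series_id,
      organism = s$organism,
      entity_kind = s$entity_kind,
      entity_name = s$entity_name,
      up_genes = as.list(s$up_genes[[1]]),
      down_genes = as.list(s$down_genes[[1]])
    )
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read a signature collection from paired GMT files
#'
#' One GMT file holds the up-regulated sets and the other the
#' down-regulated sets; the set name encodes the signature id and both files
#' must contain exactly the same names. GMT lines are the standard
#' tab-separated `name<TAB>description<TAB>gene...` records.
#'
#' @param up_path,down_path Paths to the up- and down-set GMT files.
#' @param entity_kind Optional kind override applied to all signatures.
#' @return Validated signature tibble.
#' @export
read_gmt_pair <- function(up_path, down_path, entity_kind = NULL) {
  up <- read_gmt(up_path)
  dn <- read_gmt(down_path)
  only_up <- setdiff(names(up), names(dn))
  only_dn <- setdiff(names(dn), names(up))
  if (length(only_up) || length(only_dn)) {
    abort(paste0(
      "GMT files do not share the same signature ids; orphans: ",
      paste(c(only_up, only_dn), collapse = ", ")))
  }
  rows <- lapply(names(up), function(id) {
    ges_signature(id, up_genes = up[[id]], down_genes = dn[[id]],
                  entity_kind = entity_kind)
  })
  validate_signatures(bind_rows(rows))
}

read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # name + description minimum; an empty gene list is legal for one
  # direction of an up/down pair
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    abort(paste0("GMT lines with fewer than 2 fields in ", path, ": ",
                 paste(which(bad), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) normalize_gene_symbols(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write a signature collection as paired GMT files
#'
#' @param signatures Signature tibble.
#' @param up_path,down_path Output paths for the up- and down-set files.
#' @export
write_gmt_pair <- function(signatures, up_path, down_path) {
  write_gmt(setNames(signatures$up_genes, signatures$signature_id), up_path)
  write_gmt(setNames(signatures$down_genes, signatures$signature_id), down_path)
  invisible(c(up_path, down_path))
}

#' Write named gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "gesreversal") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
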