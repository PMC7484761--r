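# Plain-text interchange formats: quant-table TSV (empty cell = missing),
# ortholog TSV, GMT gene sets, long-format compound rankings, .grp query files.

#' Read / write a protein quantification table
#'
#' TSV dialect: columns `protein_id`, `gene_symbol`, `n_peptides`,
#' `contaminant` (0/1), then one column per sample named `<GROUP>_<replicate>`;
#' an empty cell is a missing measurement.
#'
#' @param quant a quant tibble.
#' @param path file path.
#' @return `read_quant_tsv()` returns the quant tibble; `write_quant_tsv()`
#'   returns `path` invisibly.
#' @export
write_quant_tsv <- function(quant, path) {
  out <- quant
  out$contaminant <- as.integer(out$contaminant)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_quant_tsv
#' @export
read_quant_tsv <- function(path) {
  quant <- readr::read_tsv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      gene_symbol = readr::col_character(),
      n_peptides = readr::col_integer(),
      contaminant = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  quant$contaminant <- quant$contaminant > 0
  quant
}

#' Read / write an ortholog mapping table
#'
#' TSV with columns `mouse_protein_id`, `mouse_gene`, `human_gene`.
#'
#' @param map mapping tibble.
#' @param path file path.
#' @export
write_ortholog_tsv <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_ortholog_tsv
#' @export
read_ortholog_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled; defaults to `"na"`).
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- purrr::map2_chr(names(sets), seq_along(sets), function(nm, i) {
    paste(c(nm, descriptions[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, function(p) p[-(1:2)])
  names(sets) <- purrr::map_chr(parts, 1)
  sets
}

#' Read / write a compound-signature ranking database
#'
#' Long-format TSV with columns `compound`, `instance_id`, `gene`, `rank`
#' (rank 1 = most up-regulated by the compound in that instance).
#'
#' @param db a `compound_db` (or its `profiles` tibble).
#' @param path file path.
#' @return `read_compound_tsv()` returns a `compound_db`.
#' @export
write_compound_tsv <- function(db, path) {
  profiles <- if (inherits(db, "compound_db")) db$profiles else db
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_compound_tsv
#' @export
read_compound_tsv <- function(path) {
  profiles <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      compound = readr::col_character(),
      instance_id = readr::col_character(),
      gene = readr::col_character(),
      rank = readr::col_integer()
    )
  )
  structure(list(profiles = profiles, universe = sort(unique(profiles$gene))),
            class = "compound_db")
}

#' Read / write .grp query gene lists
#'
#' One gene symbol per line — the query-file convention of connectivity-map
#' style tools.
#'
#' @param genes character vector.
#' @param path file path.
#' @export
write_grp <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_grp
#' @export
read_grp <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' Write every synthetic input of a study to a directory
#'
#' Materialises a simulated dataset as the plain-text files the pipeline
#' readers consume: the quant table, an ortholog map, and (when given) a
#' compound database and GMT collection. Everything round-trips losslessly
#' through the corresponding `read_*` functions.
#'
#' @param study a `dkd_study`.
#' @param dir output directory (created if needed).
#' @param ortholog optional mapping tibble (default: 1:1 map of the study).
#' @param compound_db optional `compound_db`.
#' @param gene_sets optional named list of gene sets.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(study, dir, ortholog = NULL, compound_db = NULL,
                           gene_sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  paths <- c(quant = file.path(dir, "quant.tsv"),
             ortholog = file.path(dir, "ortholog_map.tsv"))
  write_quant_tsv(study$quant, paths[["quant"]])
  if (is.null(ortholog)) ortholog <- simulate_ortholog_map(study)
  write_ortholog_tsv(ortholog, paths[["ortholog"]])
  if (!is.null(compound_db)) {
    paths[["compound_db"]] <- file.path(dir, "compound_db.tsv")
    write_compound_tsv(compound_db, paths[["compound_db"]])
  }
  if (!is.null(gene_sets)) {
    paths[["gene_sets"]] <- file.path(dir, "gene_sets.gmt")
    write_gmt(gene_sets, paths[["gene_sets"]])
  }
  invisible(paths)
}
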