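#' Convert a mouse protein signature into a human up/down gene query
#'
#' Maps each mouse protein id through an ortholog table
#' (`mouse_protein_id`, `mouse_gene`, `human_gene`) to human gene symbols.
#' Ids with no table entry are dropped and counted as unmapped. Ids reaching
#' more than one distinct human symbol are ambiguous: dropped by default, or
#' expanded to all targets. If a human symbol is reached from both the up and
#' the down input (a collision), it is removed from both sides — a gene cannot
#' be simultaneously up and down in a query.
#'
#' @param up,down character vectors of mouse protein ids (disjoint).
#' @param ortholog ortholog mapping tibble (see [simulate_ortholog_map()] /
#'   [read_ortholog_tsv()]).
#' @param ambiguous `"drop"` (default) or `"expand"`.
#' @return An object of class `query_signature`: list with `up_genes`,
#'   `down_genes` (uppercase human symbols), `provenance` (tibble
#'   `protein_id`, `human_gene`, `direction`) and `mapping_log` (one-row
#'   tibble `n_unmapped`, `n_ambiguous`, `n_collided`).
#' @examples
#' map <- tibble::tibble(mouse_protein_id = c("P1", "P2"),
#'                       mouse_gene = c("Nphs2", "Podxl"),
#'                       human_gene = c("NPHS2", "PODXL"))
#' map_to_human("P1", "P2", map)
#' @export
map_to_human <- function(up, down, ortholog, ambiguous = c("drop", "expand")) {
  ambiguous <- match.arg(ambiguous)
  if (length(intersect(up, down)) > 0) {
    abort("up and down protein sets must be disjoint")
  }
  stopifnot(all(c("mouse_protein_id", "human_gene") %in% names(ortholog)))

  map_one_side <- function(ids, direction) {
    hits <- ortholog[ortholog$mouse_protein_id %in% ids, ]
    hits <- dplyr::distinct(hits, .data$mouse_protein_id, .data$human_gene)
    n_targets <- table(hits$mouse_protein_id)
    unmapped <- setdiff(ids, hits$mouse_protein_id)
    ambiguous_ids <- names(n_targets)[n_targets > 1]
    if (ambiguous == "drop") {
      hits <- hits[!hits$mouse_protein_id %in% ambiguous_ids, ]
    }
    list(prov = tibble::tibble(protein_id = hits$mouse_protein_id,
                               human_gene = toupper(hits$human_gene),
                               direction = direction),
         n_unmapped = length(unmapped),
         n_ambiguous = length(ambiguous_ids))
  }

  u <- map_one_side(up, "up")
  d <- map_one_side(down, "down")
  up_genes <- unique(u$prov$human_gene)
  down_genes <- unique(d$prov$human_gene)
  collided <- intersect(up_genes, down_genes)
  up_genes <- setdiff(up_genes, collided)
  down_genes <- setdiff(down_genes, collided)
  if (length(up_genes) == 0 || length(down_genes) == 0) {
    abort(paste("mapping produced an empty up or down gene set;",
                "use a larger signature or a more complete ortholog table"))
  }
  structure(list(
    up_genes = up_genes,
    down_genes = down_genes,
    provenance = dplyr::bind_rows(u$prov, d$prov) |>
      dplyr::filter(!.data$human_gene %in% collided),
    mapping_log = tibble::tibble(
      n_unmapped = u$n_unmapped + d$n_unmapped,
      n_ambiguous = u$n_ambiguous + d$n_ambiguous,
      n_collided = length(collided)
    )
  ), class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("<query_signature> %d up / %d down human gene symbols\n",
              length(x$up_genes), length(x$down_genes)))
  log <- x$mapping_log
  cat(sprintf("  dropped: %d unmapped, %d ambiguous, %d up/down collisions\n",
              log$n_unmapped, log$n_ambiguous, log$n_collided))
  invisible(x)
}

#' Write the .grp query files of a signature
#'
#' @param query a `query_signature`.
#' @param dir output directory.
#' @return Paths to `up.grp` and `down.grp`, invisibly.
#' @export
write_query_grp <- function(query, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(up = file.path(dir, "up.grp"), down = file.path(dir, "down.grp"))
  write_grp(query$up_genes, paths[["up"]])
  write_grp(query$down_genes, paths[["down"]])
  invisible(paths)
}
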