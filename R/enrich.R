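#' Hypergeometric upper-tail overlap p-value
#'
#' Probability of observing at least `x` genes shared between a query of size
#' `k` and a gene set of size `m` when the query is drawn at random from a
#' universe of `u` genes: `P(X >= x)` for
#' `X ~ Hypergeometric(u, m, k)` (the "Compute Overlaps" convention).
#'
#' @param k query size.
#' @param m gene-set size.
#' @param x observed overlap.
#' @param u universe size.
#' @return Upper-tail p-value.
#' @examples
#' hypergeom_overlap_p(k = 5, m = 5, x = 4, u = 20)
#' @export
hypergeom_overlap_p <- function(k, m, x, u) {
  stopifnot(is_count(k, 0L), is_count(m, 0L), is_count(x, 0L), is_count(u, 1L))
  if (x > min(k, m) || k > u || m > u) {
    abort("inconsistent counts: need x <= min(k, m) and k, m <= u")
  }
  phyper(x - 1, m, u - m, k, lower.tail = FALSE)
}

#' Gene-set overlap enrichment of a query signature
#'
#' Tests each set of a GMT-style collection for overlap with the query using
#' the hypergeometric upper tail, with Benjamini–Hochberg FDR across all
#' tested sets. The universe defaults to the union of all genes in the
#' collection (sets and query are intersected with it).
#'
#' @param query_genes character vector of gene symbols.
#' @param gene_sets named list of character vectors, or a path to a GMT file.
#' @param universe optional explicit gene universe.
#' @return Tibble sorted by `fdr_q` then `p_value`: `set_name`, `set_size`,
#'   `overlap_size`, `overlap_genes` (list column), `p_value`, `fdr_q`.
#' @export
enrich_overlap <- function(query_genes, gene_sets, universe = NULL) {
  if (is.character(gene_sets) && length(gene_sets) == 1) {
    gene_sets <- read_gmt(gene_sets)
  }
  if (length(gene_sets) == 0) abort("empty gene-set collection")
  if (length(query_genes) == 0) abort("empty query")
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  query <- unique(intersect(query_genes, universe))
  if (length(query) == 0) {
    abort("query has no genes in the analysis universe")
  }
  u <- length(universe)
  k <- length(query)
  rows <- purrr::imap(gene_sets, function(genes, nm) {
    genes <- unique(intersect(genes, universe))
    ov <- intersect(query, genes)
    tibble::tibble(
      set_name = nm,
      set_size = length(genes),
      overlap_size = length(ov),
      overlap_genes = list(sort(ov)),
      p_value = hypergeom_overlap_p(k, length(genes), length(ov), u)
    )
  }) |> purrr::list_rbind()
  rows$fdr_q <- p.adjust(rows$p_value, method = "BH")
  dplyr::arrange(rows, .data$fdr_q, .data$p_value, .data$set_name)
}

#' Write an enrichment table as TSV
#'
#' @param enrichment tibble from [enrich_overlap()].
#' @param path file path.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  out <- enrichment
  out$overlap_genes <- purrr::map_chr(out$overlap_genes, paste, collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
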