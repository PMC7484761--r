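# In-code fixtures shared across test files.

# hand-built quant tibble from an intensity matrix whose columns are already
# named "<GROUP>_<rep>"
make_quant <- function(m, n_peptides = NULL, contaminant = NULL) {
  n <- nrow(m)
  tibble::tibble(
    protein_id = sprintf("P%03d", seq_len(n)),
    gene_symbol = sprintf("Gs%03d", seq_len(n)),
    n_peptides = n_peptides %||% rep(3L, n),
    contaminant = contaminant %||% rep(FALSE, n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

# four-group matrix column names
group_cols <- function(n_rep = 8, groups = c("WT", "DKD", "DKD+R", "WT+R")) {
  paste(rep(groups, each = n_rep), seq_len(n_rep), sep = "_")
}

# minimal comparison-result tibble for the selection logic
make_result <- function(ids, log2fc, significant, comparison = "SetX") {
  tibble::tibble(protein_id = ids, comparison = comparison,
                 log2fc = log2fc, p_value = ifelse(significant, 0.01, 0.5),
                 significant = significant)
}

# small, fast default study for unit tests (overridable defaults)
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 300, n_dkd_effect = 60, n_ramipril_only = 10),
    list(...)
  )
  do.call(study_config, args)
}

# fixed 50+50 query over a disjoint synthetic human gene universe
toy_query <- function(n_up = 50, n_down = 50) {
  list(up_genes = sprintf("UP%03d", seq_len(n_up)),
       down_genes = sprintf("DN%03d", seq_len(n_down)))
}

`%||%` <- rlang::`%||%`
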