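# Shared helpers for the proteins-by-samples quant-table layout.
#
# A quant table is a tibble with annotation columns protein_id, gene_symbol,
# n_peptides, contaminant followed by one numeric column per sample named
# "<GROUP>_<replicate>" (e.g. "DKD+R_3"); NA = missing measurement.

QUANT_ANNOT <- c("protein_id", "gene_symbol", "n_peptides", "contaminant")

#' Sample columns of a quant table
#'
#' @param quant a quant tibble.
#' @return Character vector of sample column names (everything that is not a
#'   protein annotation column).
#' @export
sample_columns <- function(quant) {
  setdiff(names(quant), QUANT_ANNOT)
}

#' Group labels of samples
#'
#' Samples are named `<GROUP>_<replicate>`; the group is everything before the
#' final underscore-number suffix.
#'
#' @param samples character vector of sample names.
#' @return Character vector of group labels, same length as `samples`.
#' @export
sample_group <- function(samples) {
  sub("_[0-9]+$", "", samples)
}

#' Study design of a quant table
#'
#' @param quant a quant tibble.
#' @return A tibble with columns `sample` and `group`.
#' @export
study_design <- function(quant) {
  s <- sample_columns(quant)
  tibble::tibble(sample = s, group = sample_group(s))
}

# intensity matrix (proteins x samples) from a quant tibble
quant_matrix <- function(quant) {
  m <- as.matrix(quant[, sample_columns(quant), drop = FALSE])
  rownames(m) <- quant$protein_id
  m
}

# replace the sample columns of `quant` with matrix `m` (same dims/order)
set_quant_matrix <- function(quant, m) {
  quant[, sample_columns(quant)] <- tibble::as_tibble(m)
  quant
}

check_groups <- function(quant, groups) {
  present <- unique(sample_group(sample_columns(quant)))
  missing <- setdiff(groups, present)
  if (length(missing) > 0) {
    abort(sprintf("group(s) not present in table: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}

is_frac <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}
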