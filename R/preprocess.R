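#' Remove contaminant and low-evidence protein entries
#'
#' Drops rows flagged as potential contaminants and rows identified by fewer
#' than `min_peptides` peptides, preserving the order of the survivors. This
#' is the identification-level filter applied once, before any comparison.
#'
#' @param quant a quant tibble.
#' @param min_peptides minimum peptide count (default 2).
#' @return The filtered quant tibble.
#' @export
filter_proteins <- function(quant, min_peptides = 2) {
  dplyr::filter(quant, !.data$contaminant, .data$n_peptides >= min_peptides)
}

#' Median-normalize sample columns
#'
#' On the log2 scale, each sample column is shifted so that all column medians
#' (over observed values) equal the grand median of the pre-normalization
#' column medians; on the raw scale this is a per-sample scaling factor.
#' Missing cells stay missing. The operation is idempotent, and downstream
#' two-sample t-statistics are invariant to the choice of common target.
#'
#' @param quant a quant tibble.
#' @return The normalized quant tibble.
#' @export
median_normalize <- function(quant) {
  m <- quant_matrix(quant)
  obs <- colSums(!is.na(m))
  if (any(obs == 0)) {
    abort(sprintf("sample(s) with no observed values: %s",
                  paste(colnames(m)[obs == 0], collapse = ", ")))
  }
  med <- apply(log2(m), 2, median, na.rm = TRUE)
  target <- median(med)
  m <- sweep(m, 2, 2^(target - med), `*`)
  set_quant_matrix(quant, m)
}

#' Per-comparison quantification filter
#'
#' A protein enters a two-group comparison only if it was quantified (an
#' intensity value is present) in at least `min_obs` biological replicates in
#' at least one of the two groups. The mask depends only on the missingness
#' pattern, never on intensity magnitudes.
#'
#' @param quant a quant tibble.
#' @param group_a,group_b group labels.
#' @param min_obs minimum observed replicates in one group (default 4).
#' @return Named logical vector (names = `protein_id`): `TRUE` = retained.
#' @export
quantification_filter <- function(quant, group_a, group_b, min_obs = 4) {
  check_groups(quant, c(group_a, group_b))
  m <- quant_matrix(quant)
  grp <- sample_group(colnames(m))
  n_a <- rowSums(!is.na(m[, grp == group_a, drop = FALSE]))
  n_b <- rowSums(!is.na(m[, grp == group_b, drop = FALSE]))
  setNames(n_a >= min_obs | n_b >= min_obs, quant$protein_id)
}

#' Impute missing values with per-run low-percentile noise
#'
#' Within each analytical run (one sample column: each sample was injected
#' once), every missing cell is replaced by a constant noise value — the 1%
#' percentile of that run's observed protein intensities. This models the
#' left-censored (MNAR) nature of label-free missingness: values are missing
#' mostly because they fell below detection.
#'
#' @param quant a quant tibble.
#' @param percentile percentile of the observed population used as the noise
#'   constant (default 0.01).
#' @param type quantile convention passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @return The quant tibble with no missing sample cells.
#' @export
impute_noise <- function(quant, percentile = 0.01, type = 7) {
  m <- quant_matrix(quant)
  obs <- colSums(!is.na(m))
  if (any(obs == 0)) {
    abort(sprintf("run(s) with no observed values cannot be imputed: %s",
                  paste(colnames(m)[obs == 0], collapse = ", ")))
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) {
      m[miss, j] <- quantile(m[!miss, j], percentile, type = type, names = FALSE)
    }
  }
  set_quant_matrix(quant, m)
}

#' Missingness report
#'
#' Per-run missing fractions (over the rows of the supplied table) and their
#' mean, before imputation.
#'
#' @param quant a quant tibble.
#' @return A list of class `preprocess_report`: `n_proteins`, `per_run`
#'   (tibble `sample`, `group`, `n_missing`, `frac_missing`), `mean_missing`,
#'   `n_missing_cells`.
#' @export
missing_report <- function(quant) {
  m <- quant_matrix(quant)
  per_run <- tibble::tibble(
    sample = colnames(m),
    group = sample_group(colnames(m)),
    n_missing = unname(colSums(is.na(m))),
    frac_missing = unname(colMeans(is.na(m)))
  )
  structure(list(n_proteins = nrow(m),
                 per_run = per_run,
                 mean_missing = mean(per_run$frac_missing),
                 n_missing_cells = sum(per_run$n_missing)),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d proteins, %d runs\n",
              x$n_proteins, nrow(x$per_run)))
  cat(sprintf("  missing cells: %d (mean per-run fraction %.2f%%)\n",
              x$n_missing_cells, 100 * x$mean_missing))
  invisible(x)
}
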