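# The three pairwise group comparisons of the study design. In each pair the
# first-listed group is the "A" side, so log2fc = mean(A) - mean(B).
COMPARISONS <- list(
  Set1 = c("DKD", "WT"),      # disease effect
  Set2 = c("DKD+R", "DKD"),   # ramipril effect in diabetic animals
  Set3 = c("WT+R", "WT")      # ramipril effect in non-diabetic animals
)

#' Two-sample Welch (or Student) t-test on log2 intensities
#'
#' Thin wrapper around [stats::t.test()] returning the per-protein statistics
#' used throughout the pipeline. Values are expected on the log2 scale;
#' `log2fc = mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors (log2 intensities) for the two groups.
#' @param var_equal `FALSE` (default) for Welch–Satterthwaite, `TRUE` for
#'   Student.
#' @return One-row tibble: `log2fc`, `t_stat`, `df`, `p_value`. If either
#'   group has fewer than 2 values all statistics are `NA` (the protein is
#'   excluded downstream).
#' @examples
#' welch_test(c(10, 11, 12, 13), c(14, 15, 16, 18))
#' @export
welch_test <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(tibble::tibble(log2fc = NA_real_, t_stat = NA_real_,
                          df = NA_real_, p_value = NA_real_))
  }
  fc <- mean(a) - mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: no within-group variability; identical means = no evidence
    if (fc == 0) {
      return(tibble::tibble(log2fc = 0, t_stat = 0, df = length(a) + length(b) - 2,
                            p_value = 1))
    }
    return(tibble::tibble(log2fc = fc, t_stat = sign(fc) * Inf,
                          df = length(a) + length(b) - 2, p_value = 0))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  tibble::tibble(log2fc = fc,
                 t_stat = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Differential abundance for one group comparison
#'
#' Runs the paper-order processing for one two-group comparison on an
#' identification-filtered, median-normalized table: apply the per-comparison
#' quantification filter, impute remaining missing values with per-run
#' low-percentile noise, Welch-test every retained protein on the log2 scale,
#' and annotate Benjamini–Hochberg q-values over the retained set.
#'
#' @param quant a quant tibble (after [filter_proteins()] and
#'   [median_normalize()]).
#' @param comparison `"Set1"` (DKD vs WT), `"Set2"` (DKD+R vs DKD), `"Set3"`
#'   (WT+R vs WT), or a length-2 character vector `c(group_a, group_b)`.
#' @param alpha significance level (default 0.05).
#' @param select `"p"` (default; raw p < alpha flags significance, as in the
#'   source analysis) or `"q"` (BH q < alpha).
#' @param test `"welch"` (default) or `"student"`.
#' @param min_obs quantification-filter threshold (default 4).
#' @param percentile,quantile_type imputation convention, see [impute_noise()].
#' @return Tibble with one row per retained protein: `protein_id`,
#'   `gene_symbol`, `comparison`, `log2fc`, `t_stat`, `df`, `p_value`,
#'   `q_value`, `n_obs_a`, `n_obs_b`, `significant`. Volcano-plot ready
#'   (see [plot_volcano()]).
#' @export
run_comparison <- function(quant, comparison = "Set1", alpha = 0.05,
                           select = c("p", "q"), test = c("welch", "student"),
                           min_obs = 4, percentile = 0.01, quantile_type = 7) {
  select <- match.arg(select)
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(comparison) && length(comparison) == 1) {
    if (!comparison %in% names(COMPARISONS)) {
      abort(sprintf("unknown comparison '%s' (use %s or c(group_a, group_b))",
                    comparison, paste(names(COMPARISONS), collapse = ", ")))
    }
    cmp_id <- comparison
    groups <- COMPARISONS[[comparison]]
  } else {
    stopifnot(length(comparison) == 2)
    cmp_id <- paste(comparison, collapse = "_vs_")
    groups <- comparison
  }
  check_groups(quant, groups)

  mask <- quantification_filter(quant, groups[1], groups[2], min_obs = min_obs)
  design <- study_design(quant)
  keep_samples <- design$sample[design$group %in% groups]
  sub <- quant[mask, c(QUANT_ANNOT, keep_samples)]
  if (nrow(sub) == 0) {
    return(tibble::tibble(protein_id = character(), gene_symbol = character(),
                          comparison = character(), log2fc = double(),
                          t_stat = double(), df = double(), p_value = double(),
                          q_value = double(), n_obs_a = integer(),
                          n_obs_b = integer(), significant = logical()))
  }

  m_raw <- quant_matrix(sub)
  grp <- sample_group(colnames(m_raw))
  n_obs_a <- rowSums(!is.na(m_raw[, grp == groups[1], drop = FALSE]))
  n_obs_b <- rowSums(!is.na(m_raw[, grp == groups[2], drop = FALSE]))

  m <- log2(quant_matrix(impute_noise(sub, percentile = percentile,
                                      type = quantile_type)))
  idx_a <- which(grp == groups[1])
  idx_b <- which(grp == groups[2])
  stats_tbl <- purrr::map(seq_len(nrow(m)), function(i) {
    welch_test(m[i, idx_a], m[i, idx_b], var_equal = (test == "student"))
  }) |> purrr::list_rbind()

  res <- dplyr::bind_cols(
    tibble::tibble(protein_id = sub$protein_id,
                   gene_symbol = sub$gene_symbol,
                   comparison = cmp_id),
    stats_tbl,
    tibble::tibble(n_obs_a = as.integer(n_obs_a),
                   n_obs_b = as.integer(n_obs_b))
  )
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_value) &
    (if (select == "p") res$p_value else res$q_value) < alpha
  dplyr::relocate(res, "q_value", .after = "p_value")
}

#' Run the three study comparisons
#'
#' Convenience wrapper running [run_comparison()] for Set1 (DKD vs WT),
#' Set2 (DKD+R vs DKD) and Set3 (WT+R vs WT).
#'
#' @param quant a filtered, normalized quant tibble.
#' @param ... passed on to [run_comparison()].
#' @return Named list of three result tibbles (`Set1`, `Set2`, `Set3`).
#' @export
run_all_comparisons <- function(quant, ...) {
  purrr::map(setNames(names(COMPARISONS), names(COMPARISONS)),
             function(cmp) run_comparison(quant, cmp, ...))
}
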