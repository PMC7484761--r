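#' Volcano plot of a differential-abundance result
#'
#' @param res result tibble from [run_comparison()].
#' @param alpha significance level drawn as a horizontal guide.
#' @return A ggplot object: log2 fold change vs -log10 p, significant
#'   proteins colored by direction.
#' @export
plot_volcano <- function(res, alpha = 0.05) {
  res <- dplyr::mutate(res, status = dplyr::case_when(
    .data$significant & .data$log2fc > 0 ~ "up",
    .data$significant & .data$log2fc < 0 ~ "down",
    TRUE ~ "ns"
  ))
  ggplot2::ggplot(res, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#c23b22", down = "#2b6ca3",
                                            ns = "grey40")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(res$comparison)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a connectivity-map result
#'
#' Lollipop chart of per-compound enrichment, most negative (predicted
#' reversers) first.
#'
#' @param object a `cmap_result` from [cmap_query()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cmap_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      compound = factor(.data$compound,
                                        levels = rev(.data$compound)))
  ggplot2::ggplot(df, ggplot2::aes(.data$enrichment, .data$compound,
                                   colour = .data$enrichment < 0)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$enrichment,
                                       yend = .data$compound)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2b6ca3",
                                            `FALSE` = "#c23b22"),
                                 guide = "none") +
    ggplot2::labs(x = "enrichment (negative = predicted reverser)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the signature-selection flowchart counts
#'
#' @param object a `signature_sets` object.
#' @param ... unused.
#' @return A ggplot bar chart of the ordered flowchart counts.
#' @export
autoplot.signature_sets <- function(object, ...) {
  tr <- flowchart_report(object, quiet = TRUE)
  tr <- tr[tr$step != "ri_fraction_pct", ]
  tr$step <- factor(tr$step, levels = rev(tr$step))
  ggplot2::ggplot(tr, ggplot2::aes(.data$count, .data$step)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.15,
                       size = 3) +
    ggplot2::labs(x = "proteins", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gene-set enrichment table
#'
#' @param enrichment tibble from [enrich_overlap()].
#' @param top number of sets to show.
#' @return A ggplot dot chart of -log10 FDR q for the top sets.
#' @export
plot_enrichment <- function(enrichment, top = 10) {
  df <- head(enrichment, top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$fdr_q), .data$set_name,
                                   size = .data$overlap_size)) +
    ggplot2::geom_point(colour = "#2b6ca3") +
    ggplot2::labs(x = "-log10 FDR q", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
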