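#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end workflow. All
#' ambiguities of the source analysis surface here as explicit switches with
#' their defaults: test variant (`welch`), selection mode (raw `p`), Filter-2
#' policy (`same_sign`), imputation percentile convention (type 7).
#'
#' @param study a [study_config()] to simulate from, or a path to a quant
#'   table TSV.
#' @param ortholog optional path to an ortholog TSV (default: a generated 1:1
#'   upper-casing map of the study table).
#' @param alpha significance level in (0, 1).
#' @param select `"p"` or `"q"` selection mode.
#' @param test `"welch"` or `"student"`.
#' @param filter2 RS Filter-2 policy (see [select_signatures()]).
#' @param min_obs per-comparison quantification threshold.
#' @param percentile,quantile_type imputation convention.
#' @param signature `"ri"` (default) or `"rs"`: which signature is queried
#'   against the compound database.
#' @param compound_db optional path to a compound-ranking TSV (default: a
#'   simulated database with a planted reverser and mimic).
#' @param n_genes,n_compounds,instances_per_compound,reverser_noise simulated
#'   compound-database dimensions.
#' @param n_perm permutations for the enrichment p-value.
#' @param n_null null queries for specificity.
#' @param n_reference reference queries for the CMap2-style score.
#' @param gene_sets optional path to a GMT file (default: simulated sets plus
#'   one planted subset of the query).
#' @param seed master seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(study = study_config(),
                            ortholog = NULL,
                            alpha = 0.05,
                            select = "p",
                            test = "welch",
                            filter2 = "same_sign",
                            min_obs = 4,
                            percentile = 0.01,
                            quantile_type = 7,
                            signature = "ri",
                            compound_db = NULL,
                            n_genes = 1000,
                            n_compounds = 20,
                            instances_per_compound = 4,
                            reverser_noise = 0.05,
                            n_perm = 1000,
                            n_null = 100,
                            n_reference = 100,
                            gene_sets = NULL,
                            seed = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a number in (0, 1)")
  }
  if (!select %in% c("p", "q")) abort("select must be 'p' or 'q'")
  if (!test %in% c("welch", "student")) abort("test must be 'welch' or 'student'")
  if (!filter2 %in% c("same_sign", "opposite_sign", "any")) {
    abort("filter2 must be 'same_sign', 'opposite_sign' or 'any'")
  }
  if (!signature %in% c("ri", "rs")) abort("signature must be 'ri' or 'rs'")
  if (!is_frac(percentile)) abort("percentile must be in [0, 1]")
  if (!is_count(seed, 0L)) abort("seed must be a non-negative integer")
  if (inherits(study, "study_config")) validate_study_config(study)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full signature-to-compound pipeline
#'
#' Orchestrates simulate/load, preprocessing, the three group comparisons,
#' signature selection, human query conversion, connectivity scoring (classic
#' and CMap2-style) and gene-set overlap enrichment, writing every stage
#' artifact to `outdir`: per-comparison statistics TSVs, signature and
#' flowchart-trace TSVs, `.grp` query files, connectivity and enrichment
#' tables, a missingness report and a run log echoing every flowchart count.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return An object of class `dkd_pipeline`: list with `study`, `report`,
#'   `comparisons`, `sets`, `query`, `db`, `cmap`, `cmap2`, `enrichment`,
#'   `trace`, `paths`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("glomsig_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }

  # ---- inputs ---------------------------------------------------------------
  if (inherits(config$study, "study_config")) {
    cfg <- config$study
    cfg$seed <- config$seed
    study <- simulate_study(cfg)
    quant <- study$quant
    note("simulated study: %d proteins x %d samples", nrow(quant),
         length(sample_columns(quant)))
  } else {
    study <- NULL
    quant <- read_quant_tsv(config$study)
    note("loaded study table: %d proteins x %d samples", nrow(quant),
         length(sample_columns(quant)))
  }

  # ---- preprocessing --------------------------------------------------------
  filtered <- filter_proteins(quant)
  note("identification filter: %d -> %d proteins (contaminants / <2 peptides removed)",
       nrow(quant), nrow(filtered))
  normalized <- median_normalize(filtered)
  report <- missing_report(normalized)
  note("mean per-run missing fraction: %.2f%%", 100 * report$mean_missing)

  # ---- differential abundance ----------------------------------------------
  comparisons <- run_all_comparisons(
    normalized, alpha = config$alpha, select = config$select,
    test = config$test, min_obs = config$min_obs,
    percentile = config$percentile, quantile_type = config$quantile_type
  )

  # ---- signature selection --------------------------------------------------
  sets <- select_signatures(comparisons$Set1, comparisons$Set2,
                            comparisons$Set3, filter2 = config$filter2)
  trace <- flowchart_report(sets, quiet = TRUE)
  for (i in seq_len(nrow(trace))) {
    note("%s: %s", trace$step[i], trace$count[i])
  }

  # ---- query conversion -----------------------------------------------------
  ortholog <- if (is.null(config$ortholog)) {
    simulate_ortholog_map(quant, seed = config$seed + 1L)
  } else {
    read_ortholog_tsv(config$ortholog)
  }
  sig_up <- if (config$signature == "ri") sets$ri_up else sets$rs_up
  sig_down <- if (config$signature == "ri") sets$ri_down else sets$rs_down
  query <- map_to_human(sig_up, sig_down, ortholog)
  note("query signature (%s): %d up / %d down human genes", config$signature,
       length(query$up_genes), length(query$down_genes))

  # ---- connectivity ---------------------------------------------------------
  db <- if (is.null(config$compound_db)) {
    simulate_compound_db(query, n_genes = config$n_genes,
                         n_compounds = config$n_compounds,
                         instances_per_compound = config$instances_per_compound,
                         reverser_noise = config$reverser_noise,
                         seed = config$seed + 2L)
  } else {
    read_compound_tsv(config$compound_db)
  }
  cmap <- cmap_query(db, query, n_perm = config$n_perm, n_null = config$n_null,
                     seed = config$seed + 3L)
  note("top connectivity hit: %s (enrichment %.3f, p %.4g, percent non-null %d)",
       cmap$compound[1], cmap$enrichment[1], cmap$p[1], cmap$percent_non_null[1])
  cmap2 <- cmap2_score(db, query, n_reference = config$n_reference,
                       seed = config$seed + 5L)

  # ---- enrichment -----------------------------------------------------------
  gene_sets <- if (is.null(config$gene_sets)) {
    sig_genes <- c(query$up_genes, query$down_genes)
    planted <- list(PLANTED_QUERY_SET = head(sig_genes, max(3, length(sig_genes) %/% 5)))
    simulate_gene_sets(db$universe, planted = planted, seed = config$seed + 4L)
  } else {
    read_gmt(config$gene_sets)
  }
  enrichment <- enrich_overlap(c(query$up_genes, query$down_genes), gene_sets)
  note("top enriched set: %s (FDR q %.3g)", enrichment$set_name[1],
       enrichment$fdr_q[1])

  # ---- artifacts ------------------------------------------------------------
  paths <- c(
    set1 = file.path(outdir, "set1.tsv"), set2 = file.path(outdir, "set2.tsv"),
    set3 = file.path(outdir, "set3.tsv"),
    signatures = file.path(outdir, "signatures.tsv"),
    trace = file.path(outdir, "trace.tsv"),
    missing = file.path(outdir, "missing_report.tsv"),
    cmap = file.path(outdir, "cmap_table.tsv"),
    cmap2 = file.path(outdir, "cmap2_table.tsv"),
    enrichment = file.path(outdir, "enrichment.tsv"),
    log = file.path(outdir, "run_log.txt")
  )
  readr::write_tsv(comparisons$Set1, paths[["set1"]])
  readr::write_tsv(comparisons$Set2, paths[["set2"]])
  readr::write_tsv(comparisons$Set3, paths[["set3"]])
  readr::write_tsv(signature_table(sets, comparisons), paths[["signatures"]])
  readr::write_tsv(trace, paths[["trace"]])
  readr::write_tsv(report$per_run, paths[["missing"]])
  readr::write_tsv(cmap, paths[["cmap"]])
  readr::write_tsv(cmap2, paths[["cmap2"]])
  write_enrichment_tsv(enrichment, paths[["enrichment"]])
  paths <- c(paths, write_query_grp(query, outdir))
  writeLines(log_lines, paths[["log"]])

  structure(list(study = study, report = report, comparisons = comparisons,
                 sets = sets, trace = trace, query = query, db = db,
                 cmap = cmap, cmap2 = cmap2, enrichment = enrichment,
                 paths = paths, config = config),
            class = "dkd_pipeline")
}

# long signature table: one row per protein and signature membership with the
# per-comparison statistics attached
signature_table <- function(sets, comparisons) {
  long <- tidy(sets)
  stats <- purrr::imap(comparisons, function(res, nm) {
    res |>
      dplyr::select("protein_id", "log2fc", "p_value") |>
      dplyr::rename_with(function(x) paste0(tolower(nm), "_", x),
                         c("log2fc", "p_value"))
  }) |> purrr::reduce(function(a, b) dplyr::full_join(a, b, by = "protein_id"))
  dplyr::left_join(long, stats, by = "protein_id")
}

#' @export
print.dkd_pipeline <- function(x, ...) {
  cat("<dkd_pipeline>\n")
  flowchart_report(x$sets)
  cat(sprintf("top connectivity hit: %s (enrichment %.3f)\n",
              x$cmap$compound[1], x$cmap$enrichment[1]))
  cat(sprintf("artifacts: %s\n", dirname(x$paths[["log"]])))
  invisible(x)
}

#' Replicate the study's headline selection counts from a quant table
#'
#' Runs the documented deterministic chain — identification filter, median
#' normalization, per-comparison quantification filter, low-percentile
#' imputation, per-protein two-sample tests, flowchart selection — on a
#' deposited protein quantification table (TSV dialect of
#' [read_quant_tsv()]) and returns every headline count: proteins quantified,
#' Set1 significant (up/down), Set2 significant/non-significant, the four
#' filter counts, the final RI/RS sizes, the RI fraction and the mean missing
#' percentage. Useful for checking the pipeline against a published
#' supplementary table.
#'
#' @param quant a quant tibble or path to a quant TSV.
#' @param ... passed to [run_comparison()] (test variant, alpha, ...).
#' @param filter2 RS Filter-2 policy.
#' @return One-row tibble of counts.
#' @export
replicate_counts <- function(quant, ..., filter2 = "same_sign") {
  if (is.character(quant)) quant <- read_quant_tsv(quant)
  n_input <- nrow(quant)
  filtered <- filter_proteins(quant)
  normalized <- median_normalize(filtered)
  report <- missing_report(normalized)
  comparisons <- run_all_comparisons(normalized, ...)
  sets <- select_signatures(comparisons$Set1, comparisons$Set2,
                            comparisons$Set3, filter2 = filter2)
  g <- glance(sets)
  dplyr::bind_cols(
    tibble::tibble(n_input = n_input,
                   n_quantified = nrow(filtered),
                   n_set1_up = length(sets$dkd_up),
                   n_set1_down = length(sets$dkd_down),
                   mean_missing_pct = 100 * report$mean_missing),
    g
  )
}
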