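#' Configuration of a synthetic four-group glomerular proteomics study
#'
#' Describes the simulated study: a proteins-by-samples intensity table for the
#' groups WT, DKD, DKD+R and WT+R (8 biological replicates each by default)
#' with planted disease and drug effects, missing-not-at-random (MNAR)
#' missingness, contaminant flags and peptide counts.
#'
#' Intensities are generated on the log2 scale (baseline per protein plus
#' planted group shifts plus replicate noise) and stored on the raw scale
#' (`2^x`), mirroring MaxQuant-style tables. Missingness is left-censoring-like:
#' a cell with true log2 value `x` is dropped with probability
#' `1 / (1 + exp((x - mnar_midpoint) / mnar_slope))`, so low-abundance
#' measurements are preferentially missing. The defaults were calibrated once
#' so that the mean missing fraction is close to 2% — the magnitude reported
#' for the real study this layout emulates.
#'
#' Planted effect classes (all drawn among the `n_dkd_effect` proteins with a
#' DKD-vs-WT shift):
#' * plain DKD effect: same shift in DKD and DKD+R; nothing in WT+R. These are
#'   the ramipril-insensitive truth.
#' * `frac_rs`: counter-regulated by ramipril in diabetic animals only — the
#'   DKD+R mean carries the DKD shift minus `f * shift` with
#'   `f ~ U(rs_reversal_range)`.
#' * `frac_nonspecific`: a counter-regulating ramipril shift in both DKD+R and
#'   WT+R (ramipril-responsive irrespective of disease).
#' * `n_ramipril_only` additional proteins shift in DKD+R and WT+R but have no
#'   DKD effect.
#'
#' Proteins carrying planted effects are always assigned `n_peptides >= 2` and
#' `contaminant = FALSE`, so ground-truth recovery measures the selection
#' logic, not the identification filter.
#'
#' @param n_proteins number of protein rows.
#' @param groups ordered group labels.
#' @param n_replicates replicates per group.
#' @param baseline_log2_mean,baseline_log2_sd location/scale of per-protein
#'   baseline abundance (log2 units).
#' @param n_dkd_effect number of proteins with a DKD-vs-WT effect.
#' @param effect_log2_range min/max absolute log2 effect size.
#' @param frac_rs fraction of DKD-effect proteins counter-regulated by
#'   ramipril in DKD+R only.
#' @param frac_nonspecific fraction of DKD-effect proteins with a ramipril
#'   response in WT+R too.
#' @param rs_reversal_range multiplicative range of the ramipril reversal
#'   relative to the DKD effect (1 = exact cancellation).
#' @param n_ramipril_only proteins with a ramipril effect but no DKD effect.
#' @param noise_log2_sd replicate noise sd (log2 units).
#' @param mnar_midpoint,mnar_slope logistic missingness parameters on the log2
#'   scale; `mnar_midpoint = -Inf` disables missingness.
#' @param frac_contaminant fraction of (non-planted) proteins flagged as
#'   contaminants.
#' @param peptide_lambda Poisson mean of the peptide-count distribution
#'   (counts are `max(1, Poisson(lambda))`; planted proteins get at least 2).
#' @param seed integer seed; every draw is reproducible from it.
#' @return A `study_config` list.
#' @seealso [simulate_study()]
#' @export
study_config <- function(n_proteins = 2500,
                         groups = c("WT", "DKD", "DKD+R", "WT+R"),
                         n_replicates = 8,
                         baseline_log2_mean = 25,
                         baseline_log2_sd = 2,
                         n_dkd_effect = 500,
                         effect_log2_range = c(1.5, 3),
                         frac_rs = 0.125,
                         frac_nonspecific = 0.25,
                         rs_reversal_range = c(0.8, 1.2),
                         n_ramipril_only = 50,
                         noise_log2_sd = 0.5,
                         mnar_midpoint = 19.1,
                         mnar_slope = 1,
                         frac_contaminant = 0.02,
                         peptide_lambda = 4,
                         seed = 1) {
  cfg <- list(
    n_proteins = n_proteins, groups = groups, n_replicates = n_replicates,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    n_dkd_effect = n_dkd_effect, effect_log2_range = effect_log2_range,
    frac_rs = frac_rs, frac_nonspecific = frac_nonspecific,
    rs_reversal_range = rs_reversal_range, n_ramipril_only = n_ramipril_only,
    noise_log2_sd = noise_log2_sd, mnar_midpoint = mnar_midpoint,
    mnar_slope = mnar_slope, frac_contaminant = frac_contaminant,
    peptide_lambda = peptide_lambda, seed = seed
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (!is_count(cfg$n_proteins)) abort("n_proteins must be a positive integer")
  if (!is_count(cfg$n_replicates, min = 2L)) abort("n_replicates must be >= 2")
  if (length(cfg$groups) != 4 || anyDuplicated(cfg$groups) > 0) {
    abort("groups must be 4 distinct labels (WT, DKD, DKD+ramipril, WT+ramipril)")
  }
  if (!is_count(cfg$n_dkd_effect, min = 0L)) abort("n_dkd_effect must be a non-negative integer")
  if (!is_count(cfg$n_ramipril_only, min = 0L)) abort("n_ramipril_only must be a non-negative integer")
  for (f in c("frac_rs", "frac_nonspecific", "frac_contaminant")) {
    if (!is_frac(cfg[[f]])) abort(sprintf("%s must be in [0, 1]", f))
  }
  if (cfg$frac_rs + cfg$frac_nonspecific > 1) {
    abort("frac_rs + frac_nonspecific must be <= 1 (effect classes are disjoint)")
  }
  if (length(cfg$effect_log2_range) != 2 || cfg$effect_log2_range[1] <= 0 ||
      diff(cfg$effect_log2_range) < 0) {
    abort("effect_log2_range must be 0 < min <= max")
  }
  if (cfg$n_dkd_effect + cfg$n_ramipril_only + 2 > cfg$n_proteins) {
    abort("n_proteins too small for the requested planted effects")
  }
  if (cfg$noise_log2_sd <= 0) abort("noise_log2_sd must be positive")
  if (cfg$mnar_slope <= 0) abort("mnar_slope must be positive")
  invisible(cfg)
}

#' Simulate a four-group glomerular proteomics study with planted truth
#'
#' Generates a MaxQuant-style protein quantification table (raw-scale
#' intensities, empty cells where MNAR missingness struck, contaminant flags,
#' peptide counts) together with the ground-truth protein sets behind it.
#'
#' @param config a [study_config()].
#' @return An object of class `dkd_study`: a list with
#'   \describe{
#'     \item{quant}{tibble `protein_id`, `gene_symbol`, `n_peptides`,
#'       `contaminant`, then one column per sample (`<GROUP>_<rep>`).}
#'     \item{truth}{list of protein-id sets: `dkd_true_up`, `dkd_true_down`,
#'       `rs_true`, `nonspecific_true`, `ramipril_only_true`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' study <- simulate_study(study_config(n_proteins = 200, n_dkd_effect = 40))
#' study
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  set.seed(config$seed)
  n <- config$n_proteins
  samples <- paste(rep(config$groups, each = config$n_replicates),
                   seq_len(config$n_replicates), sep = "_")

  protein_id <- sprintf("P%05d", seq_len(n))
  # mouse-style gene symbols: capitalised stem, so ortholog mapping by
  # upper-casing is faithful to the field convention (Nphs2 -> NPHS2)
  gene_symbol <- sprintf("Gs%04d", seq_len(n))

  # ---- plant effect classes -------------------------------------------------
  n_rs <- round(config$frac_rs * config$n_dkd_effect)
  n_ns <- round(config$frac_nonspecific * config$n_dkd_effect)
  planted <- sample(protein_id, config$n_dkd_effect + config$n_ramipril_only)
  dkd_ids <- planted[seq_len(config$n_dkd_effect)]
  ramipril_only <- setdiff(planted, dkd_ids)
  rs_ids <- head(dkd_ids, n_rs)
  ns_ids <- head(setdiff(dkd_ids, rs_ids), n_ns)

  dkd_sign <- sample(c(-1, 1), config$n_dkd_effect, replace = TRUE)
  dkd_mag <- runif(config$n_dkd_effect,
                   config$effect_log2_range[1], config$effect_log2_range[2])
  delta <- setNames(dkd_sign * dkd_mag, dkd_ids)

  truth <- list(
    dkd_true_up = dkd_ids[dkd_sign > 0],
    dkd_true_down = dkd_ids[dkd_sign < 0],
    rs_true = rs_ids,
    nonspecific_true = ns_ids,
    ramipril_only_true = ramipril_only
  )

  # ---- per-protein, per-group log2 means ------------------------------------
  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  mu <- matrix(baseline, nrow = n, ncol = 4,
               dimnames = list(protein_id, config$groups))
  g_dkd <- config$groups[2]; g_dkdr <- config$groups[3]; g_wtr <- config$groups[4]
  mu[dkd_ids, g_dkd] <- mu[dkd_ids, g_dkd] + delta[dkd_ids]
  mu[dkd_ids, g_dkdr] <- mu[dkd_ids, g_dkdr] + delta[dkd_ids]  # carries over unless reversed
  if (length(rs_ids) > 0) {
    f <- runif(length(rs_ids), config$rs_reversal_range[1], config$rs_reversal_range[2])
    mu[rs_ids, g_dkdr] <- mu[rs_ids, g_dkdr] - f * delta[rs_ids]
  }
  if (length(ns_ids) > 0) {
    # ramipril counter-regulates these in diabetic AND non-diabetic animals
    r <- -sign(delta[ns_ids]) *
      runif(length(ns_ids), config$rs_reversal_range[1], config$rs_reversal_range[2]) *
      abs(delta[ns_ids])
    mu[ns_ids, g_dkdr] <- mu[ns_ids, g_dkdr] + r
    mu[ns_ids, g_wtr] <- mu[ns_ids, g_wtr] + r
  }
  if (length(ramipril_only) > 0) {
    r <- sample(c(-1, 1), length(ramipril_only), replace = TRUE) *
      runif(length(ramipril_only),
            config$effect_log2_range[1], config$effect_log2_range[2])
    mu[ramipril_only, g_dkdr] <- mu[ramipril_only, g_dkdr] + r
    mu[ramipril_only, g_wtr] <- mu[ramipril_only, g_wtr] + r
  }

  # ---- replicate values, MNAR dropout ---------------------------------------
  grp_of_sample <- sample_group(samples)
  x <- mu[, grp_of_sample, drop = FALSE] +
    matrix(rnorm(n * length(samples), 0, config$noise_log2_sd),
           nrow = n)
  colnames(x) <- samples
  p_miss <- plogis((config$mnar_midpoint - x) / config$mnar_slope)
  x[matrix(runif(length(x)), nrow = n) < p_miss] <- NA_real_

  # ---- annotations ----------------------------------------------------------
  n_peptides <- pmax(1L, rpois(n, config$peptide_lambda))
  contaminant <- runif(n) < config$frac_contaminant
  idx_planted <- protein_id %in% planted
  n_peptides[idx_planted] <- pmax(2L, n_peptides[idx_planted])
  contaminant[idx_planted] <- FALSE

  quant <- tibble::tibble(
    protein_id = protein_id,
    gene_symbol = gene_symbol,
    n_peptides = n_peptides,
    contaminant = contaminant
  )
  quant <- dplyr::bind_cols(quant, tibble::as_tibble(2^x))

  structure(list(quant = quant, truth = truth, config = config),
            class = "dkd_study")
}

#' @export
print.dkd_study <- function(x, ...) {
  d <- study_design(x$quant)
  cat(sprintf("<dkd_study> %d proteins x %d samples (%s)\n",
              nrow(x$quant), nrow(d),
              paste(unique(d$group), collapse = ", ")))
  cat(sprintf("  planted: %d DKD-effect (%d up / %d down), %d reversed, %d non-specific, %d ramipril-only\n",
              length(x$truth$dkd_true_up) + length(x$truth$dkd_true_down),
              length(x$truth$dkd_true_up), length(x$truth$dkd_true_down),
              length(x$truth$rs_true), length(x$truth$nonspecific_true),
              length(x$truth$ramipril_only_true)))
  frac <- mean(is.na(quant_matrix(x$quant)))
  cat(sprintf("  missing cells: %.2f%%; %d contaminant-flagged\n",
              100 * frac, sum(x$quant$contaminant)))
  invisible(x)
}

#' Simulate a mouse-to-human ortholog mapping table
#'
#' By default every mouse gene symbol maps 1:1 to its upper-cased human
#' symbol. Optional rates introduce unmapped ids (absent from the table) and
#' one-to-many mappings (a second human target with a "B" suffix).
#'
#' @param x a `dkd_study`, a quant tibble, or a character vector of mouse
#'   protein ids.
#' @param genes mouse gene symbols parallel to the protein ids (taken from the
#'   table when `x` is a study/table).
#' @param p_unmapped probability an id has no human ortholog.
#' @param p_multi probability an id maps to two human symbols.
#' @param seed integer seed.
#' @return Tibble `mouse_protein_id`, `mouse_gene`, `human_gene`.
#' @examples
#' simulate_ortholog_map(c("P1", "P2"), genes = c("Nphs2", "Podxl"))
#' @export
simulate_ortholog_map <- function(x, genes = NULL, p_unmapped = 0,
                                  p_multi = 0, seed = 1) {
  if (inherits(x, "dkd_study")) x <- x$quant
  if (is.data.frame(x)) {
    genes <- x$gene_symbol
    x <- x$protein_id
  }
  if (length(x) == 0) abort("protein id list is empty")
  if (is.null(genes)) genes <- x
  stopifnot(is_frac(p_unmapped), is_frac(p_multi), length(genes) == length(x))
  set.seed(seed)
  u <- runif(length(x))
  keep <- u >= p_unmapped
  multi <- keep & (runif(length(x)) < p_multi)
  map <- tibble::tibble(
    mouse_protein_id = x[keep],
    mouse_gene = genes[keep],
    human_gene = toupper(genes[keep])
  )
  if (any(multi)) {
    map <- dplyr::bind_rows(map, tibble::tibble(
      mouse_protein_id = x[multi],
      mouse_gene = genes[multi],
      human_gene = paste0(toupper(genes[multi]), "B")
    ))
  }
  dplyr::arrange(map, .data$mouse_protein_id, .data$human_gene)
}

#' Simulate a compound-signature ranking database with a planted reverser
#'
#' Builds per-compound-instance full rankings of an `n_genes` universe
#' (rank 1 = most up-regulated by the compound). All compounds are random
#' decoys except two: a planted `"reverser"` that ranks the query's down-genes
#' near the top and its up-genes near the bottom (the profile a compound
#' opposing the query signature would show), and a planted `"mimic"` doing the
#' opposite. `reverser_noise` is the fraction of signature genes misplaced to
#' a uniform random position in each planted instance.
#'
#' @param query a query signature (see [map_to_human()]) or a list with
#'   `up_genes` and `down_genes` character vectors.
#' @param n_genes size of the gene universe; must be at least twice the query
#'   size. The universe is the query genes plus generated filler symbols.
#' @param n_compounds total number of compounds including the two planted ones.
#' @param instances_per_compound signatures per compound.
#' @param reverser_noise fraction of signature genes misplaced per planted
#'   instance.
#' @param seed integer seed.
#' @return An object of class `compound_db`: list with `profiles` (long tibble
#'   `compound`, `instance_id`, `gene`, `rank`) and `universe` (character).
#' @examples
#' q <- list(up_genes = paste0("U", 1:5), down_genes = paste0("D", 1:5))
#' db <- simulate_compound_db(q, n_genes = 50, n_compounds = 4, seed = 2)
#' @export
simulate_compound_db <- function(query, n_genes = 1000, n_compounds = 20,
                                 instances_per_compound = 4,
                                 reverser_noise = 0.05, seed = 1) {
  up <- query$up_genes
  down <- query$down_genes
  sig <- c(up, down)
  if (!is_count(n_compounds, 2L)) abort("n_compounds must be >= 2 (reverser + mimic)")
  if (!is_count(instances_per_compound)) abort("instances_per_compound must be >= 1")
  if (!is_frac(reverser_noise)) abort("reverser_noise must be in [0, 1]")
  if (length(sig) == 0 || anyDuplicated(sig) > 0) {
    abort("query up/down sets must be non-empty and disjoint")
  }
  if (n_genes < 2 * length(sig)) {
    abort("n_genes must be at least twice the query signature size")
  }
  set.seed(seed)
  filler <- setdiff(sprintf("G%05d", seq_len(n_genes + length(sig))), sig)
  universe <- c(sig, filler[seq_len(n_genes - length(sig))])

  compounds <- c("reverser", "mimic",
                 if (n_compounds > 2) sprintf("decoy_%02d", seq_len(n_compounds - 2)))

  planted_ranking <- function(top, bottom) {
    mid <- sample(setdiff(universe, c(top, bottom)))
    ranking <- c(sample(top), mid, sample(bottom))
    noisy <- sig[runif(length(sig)) < reverser_noise]
    for (g in noisy) {
      ranking <- ranking[ranking != g]
      pos <- sample.int(length(ranking) + 1L, 1L)
      ranking <- append(ranking, g, after = pos - 1L)
    }
    ranking
  }

  profiles <- purrr::map(compounds, function(cmp) {
    purrr::map(seq_len(instances_per_compound), function(i) {
      ranking <- switch(cmp,
        reverser = planted_ranking(top = down, bottom = up),
        mimic = planted_ranking(top = up, bottom = down),
        sample(universe)
      )
      tibble::tibble(compound = cmp,
                     instance_id = sprintf("%s_%02d", cmp, i),
                     gene = ranking,
                     rank = seq_along(ranking))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(profiles = profiles, universe = universe),
            class = "compound_db")
}

#' @export
print.compound_db <- function(x, ...) {
  n_inst <- dplyr::n_distinct(x$profiles$instance_id)
  cat(sprintf("<compound_db> %d compounds, %d instances, %d-gene universe\n",
              dplyr::n_distinct(x$profiles$compound), n_inst,
              length(x$universe)))
  invisible(x)
}

#' Simulate a gene-set collection
#'
#' Random gene sets drawn from a universe, optionally including planted sets
#' passed in as-is (e.g. a subset of a query signature, to give the overlap
#' test a true positive).
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param set_size_range min/max random set size.
#' @param planted named list of character vectors prepended unchanged.
#' @param seed integer seed.
#' @return Named list of character vectors (a GMT-shaped collection).
#' @export
simulate_gene_sets <- function(universe, n_sets = 25,
                               set_size_range = c(10, 100),
                               planted = NULL, seed = 1) {
  stopifnot(is_count(n_sets, 0L), length(universe) >= max(set_size_range))
  set.seed(seed)
  sets <- purrr::map(seq_len(n_sets), function(i) {
    sample(universe, sample(set_size_range[1]:set_size_range[2], 1))
  })
  names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  c(planted, sets)
}
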