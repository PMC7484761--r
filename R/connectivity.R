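#' Connectivity-map Kolmogorov–Smirnov enrichment statistic
#'
#' The classic two-sided KS construction used by the original connectivity
#' map (build02): for `n` tag positions `V(1) < ... < V(n)` within a ranked
#' list of `n_total` genes,
#' `a = max_j(j/n - V(j)/n_total)` and `b = max_j(V(j)/n_total - (j-1)/n)`;
#' the statistic is `a` if `a > b`, else `-b`. Positive values mean the tags
#' concentrate at the top of the list.
#'
#' @param positions strictly increasing integer positions of the tags
#'   (1-based) within the ranked list.
#' @param n_total length of the ranked list.
#' @return A value in `[-1, 1]`.
#' @examples
#' ks_statistic(c(1, 2), 10)   #  0.8: tags at the very top
#' ks_statistic(c(9, 10), 10)  # -0.9: tags at the very bottom
#' @export
ks_statistic <- function(positions, n_total) {
  n <- length(positions)
  if (n == 0) abort("empty tag set: ks_statistic needs at least one position")
  if (any(positions != floor(positions)) || positions[1] < 1 ||
      positions[n] > n_total || is.unsorted(positions, strictly = TRUE)) {
    abort("positions must be strictly increasing integers in 1..n_total")
  }
  j <- seq_len(n)
  a <- max(j / n - positions / n_total)
  b <- max(positions / n_total - (j - 1) / n)
  if (a > b) a else -b
}

# rank lookup (gene -> rank) for one instance ranking given as an ordered
# gene vector (element 1 = rank 1 = most up-regulated)
rank_lookup <- function(ranking) {
  setNames(seq_along(ranking), ranking)
}

ks_of_genes <- function(genes, lookup) {
  pos <- unname(lookup[genes])
  if (anyNA(pos)) {
    abort(sprintf("query gene(s) absent from the ranking universe: %s",
                  paste(head(genes[is.na(pos)], 5), collapse = ", ")))
  }
  ks_statistic(sort(pos), length(lookup))
}

#' Raw connectivity score of a query against one instance profile
#'
#' Computes the KS statistic of the up-tags and of the down-tags within the
#' instance's ranking and combines them: `raw_s = ks_up - ks_down` when the
#' two have opposite signs, otherwise 0 (an incoherent profile carries no
#' connectivity evidence). Negative `raw_s` means the compound's profile
#' opposes the query — up-query genes sit low and down-query genes sit high —
#' i.e. a potential "reverser".
#'
#' @param query a `query_signature` (or list with `up_genes`, `down_genes`).
#' @param ranking ordered character vector of the instance's genes
#'   (rank 1 first).
#' @return One-row tibble `ks_up`, `ks_down`, `raw_s` (`raw_s` in `[-2, 2]`).
#' @export
instance_connectivity <- function(query, ranking) {
  lookup <- rank_lookup(ranking)
  ks_up <- ks_of_genes(query$up_genes, lookup)
  ks_down <- ks_of_genes(query$down_genes, lookup)
  raw_s <- if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
  tibble::tibble(ks_up = ks_up, ks_down = ks_down, raw_s = raw_s)
}

#' Scale raw connectivity scores across a database
#'
#' Positive raw scores are divided by the maximum positive raw score and
#' negative ones by the absolute value of the most negative, so scaled scores
#' lie in `[-1, 1]` with at least one instance at +1 (if any positive) and
#' one at -1 (if any negative).
#'
#' @param raw_s numeric vector of raw instance scores.
#' @return Numeric vector of scaled scores.
#' @export
scale_scores <- function(raw_s) {
  out <- raw_s
  pos <- raw_s > 0
  neg <- raw_s < 0
  if (any(pos)) out[pos] <- raw_s[pos] / max(raw_s[pos])
  if (any(neg)) out[neg] <- raw_s[neg] / abs(min(raw_s[neg]))
  out
}

# db -> list(rankings = named list of ordered gene vectors,
#            compound_of = named chr), validated strict permutations
db_rankings <- function(db) {
  profiles <- if (inherits(db, "compound_db")) db$profiles else db
  profiles <- dplyr::arrange(profiles, .data$instance_id, .data$rank)
  rankings <- split(profiles$gene, profiles$instance_id)
  sizes <- lengths(rankings)
  if (length(unique(sizes)) != 1 ||
      any(purrr::map_int(rankings, dplyr::n_distinct) != sizes)) {
    abort("each instance must rank the same gene universe exactly once")
  }
  compound_of <- profiles |>
    dplyr::distinct(.data$instance_id, .data$compound)
  list(rankings = rankings,
       compound_of = setNames(compound_of$compound, compound_of$instance_id))
}

# score every instance of a prepared ranking list against a query
# (lean path: also evaluated under every null/reference query)
score_rankings <- function(rankings, compound_of, query) {
  ks <- vapply(rankings, function(rk) {
    lookup <- rank_lookup(rk)
    c(ks_of_genes(query$up_genes, lookup),
      ks_of_genes(query$down_genes, lookup))
  }, numeric(2))
  ks_up <- ks[1, ]
  ks_down <- ks[2, ]
  raw_s <- ifelse(sign(ks_up) == sign(ks_down), 0, ks_up - ks_down)
  tibble::tibble(compound = unname(compound_of[names(rankings)]),
                 instance_id = names(rankings),
                 ks_up = unname(ks_up), ks_down = unname(ks_down),
                 raw_s = unname(raw_s),
                 scaled_score = scale_scores(unname(raw_s)))
}

#' Score every instance of a compound database against a query
#'
#' @param db a `compound_db` (or its long profiles tibble).
#' @param query a `query_signature`.
#' @return Tibble `compound`, `instance_id`, `ks_up`, `ks_down`, `raw_s`,
#'   `scaled_score`.
#' @export
score_instances <- function(db, query) {
  r <- db_rankings(db)
  score_rankings(r$rankings, r$compound_of, query)
}

#' Per-compound enrichment of instance scores
#'
#' All database instances are ordered by scaled score, descending (ties broken
#' by compound then instance id for determinism); the enrichment of a compound
#' is the KS statistic of its instances' positions in that ordering. Negative
#' enrichment means the compound's instances cluster at the reversing
#' (most-negative) end.
#'
#' @param scores instance score tibble from [score_instances()].
#' @return Tibble `compound`, `n`, `enrichment`.
#' @export
compound_enrichment <- function(scores) {
  ord <- dplyr::arrange(scores, dplyr::desc(.data$scaled_score),
                        .data$compound, .data$instance_id)
  ord$position <- seq_len(nrow(ord))
  ord |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(n = dplyr::n(),
                     enrichment = ks_statistic(sort(.data$position), nrow(ord)),
                     .groups = "drop")
}

#' Permutation p-value for a compound enrichment
#'
#' Estimates how likely an enrichment at least as extreme (same sign, absolute
#' value at least as large) would arise for `n` instances placed at random
#' among `m_total`, using the add-one estimator
#' `p = (r + 1) / (n_perm + 1)` so p is never exactly zero.
#'
#' @param n number of instances of the compound.
#' @param m_total total instances in the database.
#' @param enrichment_obs observed enrichment.
#' @param n_perm number of random placements (default 1000, minimum 100).
#' @param seed integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_p <- function(n, m_total, enrichment_obs, n_perm = 1000, seed = 1) {
  stopifnot(is_count(n), is_count(m_total), n <= m_total)
  if (n_perm < 100) abort("n_perm must be >= 100")
  set.seed(seed)
  r <- sum(vapply(seq_len(n_perm), function(i) {
    ks <- ks_statistic(sort(sample.int(m_total, n)), m_total)
    abs(ks) >= abs(enrichment_obs) && sign(ks) == sign(enrichment_obs)
  }, logical(1)))
  (r + 1) / (n_perm + 1)
}

#' Percent non-null support for a compound connection
#'
#' The percentage of a compound's instances whose scaled score is non-zero
#' and has the same sign as the compound's enrichment, rounded to an integer.
#'
#' @param scaled_scores the compound's scaled instance scores.
#' @param enrichment_sign sign of the compound's enrichment (+1/-1).
#' @return Integer percentage in 0..100.
#' @export
percent_non_null <- function(scaled_scores, enrichment_sign) {
  if (length(scaled_scores) == 0) abort("compound has no instances")
  supporting <- scaled_scores != 0 & sign(scaled_scores) == enrichment_sign
  as.integer(round(100 * mean(supporting)))
}

# random null query of the same up/down sizes over the universe
random_query <- function(universe, n_up, n_down) {
  g <- sample(universe, n_up + n_down)
  list(up_genes = g[seq_len(n_up)], down_genes = g[n_up + seq_len(n_down)])
}

#' Connectivity-map query summary (classic output)
#'
#' Scores every instance, scales the scores across the database, computes
#' per-compound mean score and KS enrichment, a permutation p-value, the
#' percent non-null support, and the specificity of each connection — the
#' fraction of random null queries (same up/down sizes) under which the
#' compound reaches an enrichment at least as extreme with the same sign.
#' Compounds are sorted by enrichment, ascending (the most negative — the
#' strongest predicted reversers — first), ties broken by name.
#'
#' @param db a `compound_db`.
#' @param query a `query_signature`.
#' @param n_perm permutations for the p-value (default 1000).
#' @param n_null random null queries for specificity (default 100; 0 skips
#'   specificity, reported as `NA`).
#' @param min_n instance-count threshold flagged in `n_ok` (default 4; the
#'   classic report considers compounds with at least 4 signatures).
#' @param seed integer seed for permutations and null queries.
#' @return A tibble of class `cmap_result`: `compound`, `mean`, `n`,
#'   `enrichment`, `p`, `specificity`, `percent_non_null`, `n_ok`.
#' @export
cmap_query <- function(db, query, n_perm = 1000, n_null = 100, min_n = 4,
                       seed = 1) {
  r <- db_rankings(db)
  scores <- score_rankings(r$rankings, r$compound_of, query)
  enr <- compound_enrichment(scores)
  m_total <- nrow(scores)

  mean_tbl <- scores |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(mean = mean(.data$scaled_score), .groups = "drop")

  out <- dplyr::left_join(enr, mean_tbl, by = "compound")
  out$p <- purrr::map2_dbl(out$n, out$enrichment, function(n, e) {
    permutation_p(n, m_total, e, n_perm = n_perm, seed = seed)
  })
  out$percent_non_null <- purrr::map2_int(out$compound, sign(out$enrichment),
    function(cmp, s) {
      percent_non_null(scores$scaled_score[scores$compound == cmp], s)
    })

  if (n_null > 0) {
    set.seed(seed)
    n_up <- length(query$up_genes)
    n_down <- length(query$down_genes)
    universe <- r$rankings[[1]]
    null_enr <- purrr::map(seq_len(n_null), function(i) {
      q0 <- random_query(universe, n_up, n_down)
      compound_enrichment(score_rankings(r$rankings, r$compound_of, q0))
    })
    null_mat <- purrr::map(null_enr, function(e) {
      setNames(e$enrichment, e$compound)
    })
    out$specificity <- purrr::map2_dbl(out$compound, out$enrichment,
      function(cmp, e_obs) {
        e0 <- purrr::map_dbl(null_mat, function(v) v[[cmp]])
        mean(abs(e0) >= abs(e_obs) & sign(e0) == sign(e_obs))
      })
  } else {
    out$specificity <- NA_real_
  }

  out$n_ok <- out$n >= min_n
  out <- out |>
    dplyr::select("compound", "mean", "n", "enrichment", "p", "specificity",
                  "percent_non_null", "n_ok") |>
    dplyr::arrange(.data$enrichment, .data$compound)
  class(out) <- c("cmap_result", class(out))
  out
}

# per-compound aggregated ranking: genes ordered by mean rank across the
# compound's instances, ties broken by gene name for determinism
aggregate_ranking <- function(rankings) {
  genes <- sort(rankings[[1]])
  mean_rank <- rowMeans(vapply(rankings, function(rk) {
    unname(rank_lookup(rk)[genes])
  }, numeric(length(genes))))
  genes[order(mean_rank, genes)]
}

# wtcs for all compounds under one query, given aggregated rankings
wtcs_all <- function(agg_rankings, query) {
  purrr::map_dbl(agg_rankings, function(rk) {
    lookup <- rank_lookup(rk)
    es_up <- ks_of_genes(query$up_genes, lookup)
    es_down <- ks_of_genes(query$down_genes, lookup)
    if (sign(es_up) == sign(es_down)) 0 else (es_up - es_down) / 2
  })
}

# normalize wtcs by the mean |wtcs| of same-sign compounds
normalize_wtcs <- function(wtcs) {
  ncs <- wtcs
  for (s in c(-1, 1)) {
    idx <- sign(wtcs) == s
    if (any(idx)) ncs[idx] <- wtcs[idx] / mean(abs(wtcs[idx]))
  }
  ncs
}

#' CMap2-style standardized connectivity score
#'
#' A simplified analogue of the modern connectivity-map score. Each compound's
#' instances are aggregated into one profile by mean gene rank; the weighted
#' connectivity score is `wtcs = (ES_up - ES_down) / 2` when the two tails
#' disagree in sign (else 0), normalized within same-sign compounds to `ncs`,
#' and standardized against reference queries: the score is
#' `sign(ncs) * 100 * (fraction of reference queries whose |ncs| for that
#' compound is strictly smaller than the observed |ncs|)`, ranging -100..100.
#'
#' @param db a `compound_db`.
#' @param query a `query_signature`.
#' @param n_reference number of random reference queries (default 100).
#' @param seed integer seed.
#' @return Tibble `compound`, `wtcs`, `ncs`, `score`, sorted by score
#'   ascending (strongest predicted reversers first).
#' @export
cmap2_score <- function(db, query, n_reference = 100, seed = 1) {
  if (n_reference < 1) abort("n_reference must be >= 1")
  r <- db_rankings(db)
  by_compound <- split(r$rankings, r$compound_of[names(r$rankings)])
  agg <- purrr::map(by_compound, aggregate_ranking)

  wtcs <- wtcs_all(agg, query)
  ncs <- normalize_wtcs(wtcs)

  set.seed(seed)
  universe <- r$rankings[[1]]
  n_up <- length(query$up_genes)
  n_down <- length(query$down_genes)
  ref_ncs <- vapply(seq_len(n_reference), function(i) {
    normalize_wtcs(wtcs_all(agg, random_query(universe, n_up, n_down)))
  }, numeric(length(agg)))
  if (length(agg) == 1) ref_ncs <- matrix(ref_ncs, nrow = 1)

  score <- purrr::map_dbl(seq_along(ncs), function(i) {
    if (ncs[i] == 0) return(0)
    sign(ncs[i]) * 100 * mean(abs(ref_ncs[i, ]) < abs(ncs[i]))
  })
  tibble::tibble(compound = names(agg), wtcs = unname(wtcs),
                 ncs = unname(ncs), score = score) |>
    dplyr::arrange(.data$score, .data$compound)
}
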