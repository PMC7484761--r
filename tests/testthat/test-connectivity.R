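test_that("KS statistic matches hand-evaluated values and rejects bad input", {
  expect_equal(ks_statistic(c(1, 2), 10), 0.8)
  expect_equal(ks_statistic(c(9, 10), 10), -0.9)
  expect_error(ks_statistic(integer(), 10), "empty")
  expect_error(ks_statistic(c(2, 1), 10), "strictly increasing")
  expect_error(ks_statistic(c(1, 11), 10), "strictly increasing")
})

test_that("KS statistic equals the brute-force running-sum oracle exhaustively", {
  # every tag set with n <= 3 within every list length N <= 8
  for (N in 2:8) {
    for (n in 1:min(3, N)) {
      sets <- combn(N, n)
      for (j in seq_len(ncol(sets))) {
        pos <- sets[, j]
        expect_equal(ks_statistic(pos, N), ks_oracle(pos, N),
                     info = sprintf("N=%d pos=%s", N, paste(pos, collapse = ",")))
      }
    }
  }
  # degenerate full-list tag set: assert oracle equality, not a constant
  for (N in 2:6) {
    expect_equal(ks_statistic(seq_len(N), N), ks_oracle(seq_len(N), N))
  }
})

test_that("instance connectivity sign convention and combination rule", {
  universe <- sprintf("g%03d", 1:100)
  q <- list(up_genes = universe[1:10], down_genes = universe[91:100])
  # up-query at top, down-query at bottom: positive (mimicking) score
  top <- instance_connectivity(q, universe)
  expect_gt(top$raw_s, 0)
  # the reversed ranking gives the same magnitude, opposite sign
  bottom <- instance_connectivity(q, rev(universe))
  expect_equal(bottom$raw_s, -top$raw_s)
  expect_lt(bottom$raw_s, 0)
  # both tails on the same side: zero by the combination rule
  q_same <- list(up_genes = universe[1:5], down_genes = universe[6:10])
  expect_equal(instance_connectivity(q_same, universe)$raw_s, 0)
  # unknown query gene is an explicit error
  q_bad <- list(up_genes = "nope", down_genes = universe[1:2])
  expect_error(instance_connectivity(q_bad, universe), "nope")
})

test_that("reversing every ranking negates raw scores up to list discreteness", {
  # rank reversal maps the KS terms a' = b - 1/N, b' = a + 1/N, so each tail
  # is antisymmetric within 1/N; instances whose tails sit near the a ~ b
  # boundary can legitimately flip the zero-combination rule, so the exact
  # check applies to decisively scored instances
  q <- toy_query(8, 8)
  N <- 120
  db <- simulate_compound_db(q, n_genes = N, n_compounds = 4,
                             instances_per_compound = 2, seed = 13)
  flipped <- db
  flipped$profiles <- db$profiles |>
    dplyr::group_by(.data$instance_id) |>
    dplyr::mutate(rank = rev(.data$rank)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$instance_id, .data$rank)
  s1 <- score_instances(db, q)
  s2 <- score_instances(flipped, q)
  decisive <- abs(s1$raw_s) > 4 / N & abs(s2$raw_s) > 4 / N
  expect_gt(sum(decisive), 0)
  expect_lt(max(abs(s2$raw_s[decisive] + s1$raw_s[decisive])), 2 / N + 1e-12)
})

test_that("score scaling pins the extremes to +-1", {
  expect_equal(scale_scores(c(2, 1, -1)), c(1, 0.5, -1))
  expect_equal(scale_scores(c(0, 0)), c(0, 0))
  expect_equal(scale_scores(c(-3, -1)), c(-1, -1 / 3))
  set.seed(3)
  x <- rnorm(50)
  s <- scale_scores(x)
  expect_equal(max(s), 1)
  expect_equal(min(s), -1)
  expect_true(all(s >= -1 & s <= 1))
  expect_identical(s == 0, x == 0)
})

test_that("compound enrichment reflects instance positions in the score ordering", {
  # 100 instances; compound "low" occupies the 4 lowest-scoring positions
  scores <- tibble::tibble(
    compound = c(rep("other", 96), rep("low", 4)),
    instance_id = sprintf("i%03d", 1:100),
    raw_s = c(seq(2, 1, length.out = 96), -1, -1.1, -1.2, -1.3)
  )
  scores$scaled_score <- scale_scores(scores$raw_s)
  enr <- compound_enrichment(scores)
  low <- enr$enrichment[enr$compound == "low"]
  expect_equal(low, ks_oracle(97:100, 100))
  expect_lt(low, -0.9)
  # uniformly interleaved instances have small |enrichment|
  inter <- tibble::tibble(
    compound = rep(c("a", "b"), 50),
    instance_id = sprintf("i%03d", 1:100),
    raw_s = seq(1, -1, length.out = 100)
  )
  inter$scaled_score <- scale_scores(inter$raw_s)
  e2 <- compound_enrichment(inter)
  expect_true(all(abs(e2$enrichment) < 0.1))
  # a single instance at position 1 scores exactly ks({1}, M)
  one <- tibble::tibble(compound = c("solo", rep("rest", 9)),
                        instance_id = sprintf("i%02d", 1:10),
                        raw_s = seq(1, 0.1, length.out = 10))
  one$scaled_score <- scale_scores(one$raw_s)
  e3 <- compound_enrichment(one)
  expect_equal(e3$enrichment[e3$compound == "solo"], ks_statistic(1, 10))
})

test_that("permutation p honors its estimator bounds and determinism", {
  # observed more extreme than any permutation can be counted: p = 1/(n+1)
  expect_equal(permutation_p(2, 50, -1.99, n_perm = 200, seed = 2), 1 / 201)
  # n = M: every permutation is the same placement -> p = 1
  expect_equal(permutation_p(10, 10, ks_statistic(1:10, 10),
                             n_perm = 100, seed = 3), 1)
  expect_identical(permutation_p(4, 80, -0.5, n_perm = 200, seed = 7),
                   permutation_p(4, 80, -0.5, n_perm = 200, seed = 7))
  expect_error(permutation_p(4, 80, -0.5, n_perm = 10), "n_perm")
})

test_that("percent non-null counts same-sign non-zero support", {
  expect_equal(percent_non_null(c(-0.9, -0.8, -0.7, -0.6), -1), 100)
  expect_equal(percent_non_null(c(-0.9, -0.8, 0.7, 0.6), -1), 50)
  expect_equal(percent_non_null(c(0, 0, 0), -1), 0)
  expect_equal(percent_non_null(c(0.5, 0, -0.5, 0.9), 1), 50)
})

test_that("planted reverser and mimic are recovered end to end", {
  q <- toy_query(50, 50)
  db <- simulate_compound_db(q, n_genes = 500, n_compounds = 22,
                             instances_per_compound = 4,
                             reverser_noise = 0.1, seed = 17)
  res <- cmap_query(db, q, n_perm = 500, n_null = 50, seed = 18)
  expect_equal(res$compound[1], "reverser")
  expect_lt(res$enrichment[1], 0)
  expect_equal(res$percent_non_null[1], 100L)
  expect_equal(res$p[1], 1 / 501)
  expect_lt(res$specificity[1], 0.05)
  # mimic sits at the positive extreme
  expect_equal(res$compound[nrow(res)], "mimic")
  expect_gt(res$enrichment[nrow(res)], 0)
  # reverser raw instance scores are all negative (noise well below 1)
  scores <- score_instances(db, q)
  expect_true(all(scores$raw_s[scores$compound == "reverser"] < 0))
  expect_true(all(res$n == 4), all(res$n_ok))
})

test_that("summary table is ordered by enrichment with alphabetical tie-break", {
  # score-ordering ties are resolved by (compound, instance_id) and the
  # output rows by (enrichment, compound); both orders are deterministic
  scores <- tibble::tibble(
    compound = rep(c("zeta", "alpha"), each = 2),
    instance_id = c("z1", "z2", "a1", "a2"),
    raw_s = c(1, -1, 1, -1)
  )
  scores$scaled_score <- scale_scores(scores$raw_s)
  expect_identical(compound_enrichment(scores), compound_enrichment(scores))
  q <- toy_query(3, 3)
  db <- simulate_compound_db(q, n_genes = 50, n_compounds = 2,
                             instances_per_compound = 2, seed = 19)
  res <- cmap_query(db, q, n_perm = 100, n_null = 0, seed = 20)
  expect_equal(res, dplyr::arrange(res, .data$enrichment, .data$compound))
})

test_that("cmap2 score is standardized, bounded, and flags the planted pair", {
  q <- toy_query(50, 50)
  db <- simulate_compound_db(q, n_genes = 500, n_compounds = 22,
                             instances_per_compound = 4,
                             reverser_noise = 0.05, seed = 23)
  c2 <- cmap2_score(db, q, n_reference = 50, seed = 24)
  expect_true(all(c2$score >= -100 & c2$score <= 100))
  expect_true(all(sign(c2$score) == sign(c2$ncs) | c2$score == 0))
  rev_row <- c2[c2$compound == "reverser", ]
  expect_lt(rev_row$score, -80)
  expect_lt(rev_row$wtcs, 0)
  expect_gt(c2$score[c2$compound == "mimic"], 80)
  # wtcs = 0 propagates to score 0: same-side tails
  agg_q <- list(up_genes = db$universe[1:5], down_genes = db$universe[6:10])
  c0 <- cmap2_score(db, agg_q, n_reference = 20, seed = 25)
  expect_true(all(c0$score[c0$wtcs == 0] == 0))
})

test_that("permutation p is relabel-invariant and calibrated against its own null", {
  # p depends only on (n, M, observed enrichment), never on which instances
  # carry which labels
  expect_identical(permutation_p(4, 80, -0.62, n_perm = 300, seed = 41),
                   permutation_p(4, 80, -0.62, n_perm = 300, seed = 41))
  # calibration against the estimator's own null: the estimator is a
  # sign-directed one-sided p, so under random placement of n instances
  # among M it behaves like Uniform(0, ~0.5): P(p <= alpha) ~ 2 * alpha
  set.seed(42)
  ps <- replicate(200, {
    e <- ks_statistic(sort(sample.int(24, 4)), 24)
    permutation_p(4, 24, e, n_perm = 200, seed = sample.int(1e6, 1))
  })
  for (alpha in c(0.05, 0.1, 0.2)) {
    env <- qbinom(c(0.0005, 0.9995), 200, 2 * alpha) / 200
    expect_gte(mean(ps <= alpha), env[1])
    expect_lte(mean(ps <= alpha), env[2])
  }
  # and it does reject for a genuinely extreme placement
  expect_lt(permutation_p(4, 24, -0.97, n_perm = 200, seed = 31), 0.05)
})
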