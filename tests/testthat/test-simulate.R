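test_that("simulated study has the four-group design and is seed-deterministic", {
  st <- simulate_study(small_config(seed = 11))
  expect_equal(nrow(st$quant), 300)
  d <- study_design(st$quant)
  expect_equal(nrow(d), 32)
  expect_equal(as.vector(table(d$group)[c("WT", "DKD", "DKD+R", "WT+R")]),
               rep(8L, 4))

  st2 <- simulate_study(small_config(seed = 11))
  expect_identical(st$quant, st2$quant)
  expect_identical(st$truth, st2$truth)

  st3 <- simulate_study(small_config(seed = 12))
  expect_false(identical(st$quant, st3$quant))
})

test_that("ground-truth sets match the configured counts and invariants", {
  cfg <- small_config(frac_rs = 0.2, frac_nonspecific = 0.3, seed = 4)
  st <- simulate_study(cfg)
  tr <- st$truth
  dkd <- c(tr$dkd_true_up, tr$dkd_true_down)
  expect_length(dkd, cfg$n_dkd_effect)
  expect_length(tr$rs_true, round(0.2 * cfg$n_dkd_effect))
  expect_length(tr$nonspecific_true, round(0.3 * cfg$n_dkd_effect))
  expect_length(tr$ramipril_only_true, cfg$n_ramipril_only)
  # class structure: reversed/non-specific are DKD proteins, disjoint classes
  expect_true(all(c(tr$rs_true, tr$nonspecific_true) %in% dkd))
  expect_length(intersect(tr$rs_true, tr$nonspecific_true), 0)
  expect_length(intersect(tr$ramipril_only_true, dkd), 0)
})

test_that("a study without planted effects has empty truth sets", {
  st <- simulate_study(small_config(n_dkd_effect = 0, n_ramipril_only = 0))
  expect_true(all(lengths(st$truth) == 0))
})

test_that("planted group means carry the configured shifts", {
  # no missingness, tiny noise: group means must sit near the planted values
  cfg <- study_config(n_proteins = 60, n_dkd_effect = 20, n_ramipril_only = 5,
                      frac_rs = 0.25, frac_nonspecific = 0.25,
                      rs_reversal_range = c(1, 1), noise_log2_sd = 0.05,
                      mnar_midpoint = -Inf, seed = 7)
  st <- simulate_study(cfg)
  m <- log2(as.matrix(st$quant[, sample_columns(st$quant)]))
  rownames(m) <- st$quant$protein_id
  grp <- sample_group(colnames(m))
  gm <- sapply(unique(grp), function(g) rowMeans(m[, grp == g]))
  tr <- st$truth
  dkd <- c(tr$dkd_true_up, tr$dkd_true_down)
  plain <- setdiff(dkd, c(tr$rs_true, tr$nonspecific_true))
  eff <- gm[, "DKD"] - gm[, "WT"]
  expect_true(all(abs(eff[dkd]) > 1.3))
  expect_true(all(eff[tr$dkd_true_up] > 0), all(eff[tr$dkd_true_down] < 0))
  # plain DKD effect carries over to DKD+R; full reversal cancels it
  expect_true(all(abs(gm[plain, "DKD+R"] - gm[plain, "DKD"]) < 0.2))
  expect_true(all(abs(gm[tr$rs_true, "DKD+R"] - gm[tr$rs_true, "WT"]) < 0.2))
  # non-specific proteins respond to ramipril in non-diabetic animals too
  expect_true(all(abs(gm[tr$nonspecific_true, "WT+R"] - gm[tr$nonspecific_true, "WT"]) > 1))
  # untouched proteins are flat everywhere
  null_ids <- setdiff(rownames(gm), c(dkd, tr$ramipril_only_true))
  expect_true(max(abs(gm[null_ids, "DKD"] - gm[null_ids, "WT"])) < 0.3)
})

test_that("missingness increases monotonically with the MNAR midpoint", {
  frac_at <- function(mid) {
    st <- simulate_study(small_config(mnar_midpoint = mid, seed = 3))
    mean(is.na(as.matrix(st$quant[, sample_columns(st$quant)])))
  }
  f <- vapply(c(-Inf, 18, 20, 22), frac_at, numeric(1))
  expect_equal(f[1], 0)
  expect_true(all(diff(f) > 0))
})

test_that("invalid study configurations are rejected up front", {
  expect_error(study_config(n_proteins = 0), "n_proteins")
  expect_error(study_config(frac_rs = 0.7, frac_nonspecific = 0.5), "disjoint")
  expect_error(study_config(effect_log2_range = c(2, 1)), "effect_log2_range")
  expect_error(study_config(n_proteins = 20, n_dkd_effect = 30), "too small")
})

test_that("ortholog map follows the configured mapping rates", {
  ids <- sprintf("P%03d", 1:100)
  genes <- sprintf("Gene%03da", 1:100)

  map <- simulate_ortholog_map(ids, genes = genes)
  expect_equal(nrow(map), 100)
  expect_identical(sort(map$human_gene), sort(toupper(genes)))

  # mouse capitalisation convention
  one <- simulate_ortholog_map("P1", genes = "Nphs2")
  expect_equal(one$human_gene, "NPHS2")

  set.seed(99)
  hits <- replicate(20, {
    s <- sample.int(1e6, 1)
    m <- simulate_ortholog_map(ids, genes = genes, p_multi = 0.1, seed = s)
    sum(table(m$mouse_protein_id) == 2)
  })
  expect_gt(mean(hits), 5)
  expect_lt(mean(hits), 16)

  m2 <- simulate_ortholog_map(ids, genes = genes, p_unmapped = 0.3, seed = 5)
  expect_lt(dplyr::n_distinct(m2$mouse_protein_id), 100)
  expect_error(simulate_ortholog_map(character()), "empty")
})

test_that("compound database plants a clean reverser and mimic", {
  q <- toy_query(10, 10)
  db <- simulate_compound_db(q, n_genes = 100, n_compounds = 2,
                             instances_per_compound = 3, reverser_noise = 0,
                             seed = 8)
  expect_setequal(unique(db$profiles$compound), c("reverser", "mimic"))
  expect_equal(dplyr::n_distinct(db$profiles$instance_id), 6)
  # each instance is a strict permutation of the universe
  by_inst <- split(db$profiles$gene, db$profiles$instance_id)
  expect_true(all(vapply(by_inst, function(g) setequal(g, db$universe) &&
                           !anyDuplicated(g), logical(1))))
  # zero noise: every reverser instance puts all down-genes above all up-genes
  rev_inst <- db$profiles[db$profiles$compound == "reverser", ]
  for (id in unique(rev_inst$instance_id)) {
    rk <- rev_inst[rev_inst$instance_id == id, ]
    expect_lt(max(rk$rank[rk$gene %in% q$down_genes]),
              min(rk$rank[rk$gene %in% q$up_genes]))
  }
  expect_error(simulate_compound_db(q, n_genes = 30), "twice")
})

test_that("study determinism survives a TSV round trip and fixtures are lossless", {
  st <- simulate_study(small_config(seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(st, dir,
                          compound_db = simulate_compound_db(toy_query(5, 5),
                                                             n_genes = 40,
                                                             n_compounds = 3,
                                                             seed = 2),
                          gene_sets = list(PATH1 = c("A", "B", "C")))
  back <- read_quant_tsv(paths[["quant"]])
  expect_equal(as.data.frame(back), as.data.frame(st$quant), tolerance = 1e-12)

  map <- read_ortholog_tsv(paths[["ortholog"]])
  expect_equal(map, simulate_ortholog_map(st))

  db <- read_compound_tsv(paths[["compound_db"]])
  orig <- simulate_compound_db(toy_query(5, 5), n_genes = 40, n_compounds = 3,
                               seed = 2)
  expect_equal(db$profiles, orig$profiles)

  # GMT: one line per set, tab-separated, name + description + genes
  lines <- readLines(paths[["gene_sets"]])
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]], c("PATH1", "na", "A", "B", "C"))
  expect_equal(read_gmt(paths[["gene_sets"]]), list(PATH1 = c("A", "B", "C")))
})
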