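test_that("strain_score matches the stated formula", {
  expect_equal(strain_score(100, 100, 1e5, 1e5), 0)
  expect_equal(strain_score(25, 100, 1e5, 1e5), log2(26 / 101))
  expect_equal(strain_score(0, 0, 1e5, 1e5), 0)
  # unequal totals: read-fraction normalization
  expect_equal(strain_score(10, 10, 2e5, 1e5), log2(((10 + 1) / 2e5) / ((10 + 1) / 1e5)))
  expect_error(strain_score(-1, 5, 10, 10), "negative")
  expect_error(strain_score(1, 5, 0, 10), "totals")
})

test_that("gene_score equals a brute-force weighted mean (oracle, 1000 instances)", {
  set.seed(6)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    f <- rnorm(n, 0, 2)
    w <- runif(n, 0.01, 10)
    # independent brute force: explicit loop accumulation
    num <- 0; den <- 0
    for (k in seq_len(n)) { num <- num + w[k] * f[k]; den <- den + w[k] }
    expect_equal(gene_score(f, w), num / den, tolerance = 1e-12)
  }
  expect_equal(gene_score(c(-2, -1)), -1.5)
  expect_equal(gene_score(c(-2, 0), c(3, 1)), -1.5)
  expect_equal(gene_score(1.7), 1.7)
  expect_error(gene_score(numeric(0)), "eligible")
})

test_that("strain weights are equal on balanced counts", {
  expect_equal(strain_weight(10, 10), strain_weight(10, 10))
  # gene_score reduces to plain mean when counts are balanced
  sc <- c(-1, 0, 2)
  w <- strain_weight(c(5, 5, 5), c(5, 5, 5))
  expect_equal(gene_score(sc, w), mean(sc))
})

test_that("normalize_mcs subtracts precolumn per replicate and reports coverage", {
  raw <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 3),
    sample_id = "x", condition = "std",
    fraction = rep(c("precolumn", "magnetic", "nonmagnetic"), 2),
    replicate = 1L,
    score = c(-0.5, -2.0, 0.3, -1.0, -1.0, 0.0),
    n_strains = 5L, stringsAsFactors = FALSE)
  norm <- normalize_mcs(raw)
  expect_equal(norm$mcs[norm$gene_id == "g1" & norm$fraction == "magnetic"], -1.5)
  # growth-defective but column-neutral gene: magnetic == precolumn -> 0
  expect_equal(norm$mcs[norm$gene_id == "g2" & norm$fraction == "magnetic"], 0)
  # missing precolumn -> error naming the condition
  bad <- raw[raw$fraction != "precolumn", ]
  expect_error(normalize_mcs(bad), "precolumn.*std")
  # gene absent from precolumn -> dropped and counted
  part <- raw[!(raw$gene_id == "g2" & raw$fraction == "precolumn"), ]
  norm2 <- normalize_mcs(part)
  expect_false("g2" %in% norm2$gene_id)
  expect_equal(unname(attr(norm2, "coverage")["n_dropped"]), 2L)
})

test_that("replicate_mean averages available replicates", {
  norm <- data.frame(gene_id = "g1", condition = "std", fraction = "magnetic",
                     replicate = 1:3, mcs = c(-1.2, -1.5, -1.8),
                     n_strains = 4L, stringsAsFactors = FALSE)
  m <- replicate_mean(norm)
  expect_equal(m$mean_mcs, -1.5)
  expect_equal(m$n_rep, 3L)
  expect_true(m$consistent_sign)
  single <- norm[2, ]
  expect_equal(replicate_mean(single)$mean_mcs, -1.5)
})

test_that("call_hits applies threshold, direction, and sign consistency", {
  mk_scores <- function(reps) {
    norm <- data.frame(gene_id = "g1", condition = "std", fraction = "magnetic",
                       replicate = seq_along(reps), mcs = reps,
                       n_strains = 4L, stringsAsFactors = FALSE)
    replicate_mean(norm)
  }
  h <- call_hits(mk_scores(c(-1.6, -1.5, -1.7)))
  expect_equal(h$direction, "depleted")
  expect_true(h$consistent_sign)
  # inconsistent replicates flagged, and dropped when required
  m2 <- mk_scores(c(-1.6, 0.2, -1.9))
  expect_equal(nrow(call_hits(m2, require_consistent_sign = TRUE)), 0L)
  h2 <- call_hits(m2, require_consistent_sign = FALSE)
  expect_false(h2$consistent_sign)
  expect_equal(nrow(call_hits(mk_scores(c(-0.5, -0.4, -0.6)))), 0L)
})

test_that("scoring t0 against itself yields all-zero gene scores", {
  cfg <- small_sim_config(seed = 13)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  sel <- simulate_selection(ps, sim$truth, cfg)
  cm <- sel$counts
  # rebuild a sheet in which "magnetic" and "precolumn" reuse the t0 counts
  t0 <- cm$sheet$sampleId[cm$sheet$fraction == "t0" & cm$sheet$replicate == 1]
  sheet <- cm$sheet[cm$sheet$replicate == 1 & cm$sheet$fraction != "nonmagnetic", ]
  counts <- cm$counts[, sheet$sampleId]
  counts[, sheet$sampleId[sheet$fraction == "magnetic"]] <- cm$counts[, t0]
  counts[, sheet$sampleId[sheet$fraction == "precolumn"]] <- cm$counts[, t0]
  cm2 <- magscreen:::new_count_matrix(counts, setNames(integer(3), sheet$sampleId), sheet)
  sc <- score_genes(cm2, ps$pool)
  expect_true(all(sc$raw$score == 0))
  expect_true(all(sc$norm$mcs == 0))
})

test_that("two independent draws of the same abundances score near zero", {
  cfg <- small_sim_config(seed = 14, mai_block = NULL)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  sel <- simulate_selection(ps, sim$truth, cfg)
  sc <- score_genes(sel$counts, ps$pool)
  pre <- sc$raw[sc$raw$fraction == "precolumn", ]
  expect_lt(abs(median(pre$score)), 0.05)
})

test_that("strain eligibility respects t0_min_reads and min_strains_per_gene", {
  sheet <- data.frame(sampleId = c("t0_r1", "pre_r1", "mag_r1"),
                      condition = "std", fraction = c("t0", "precolumn", "magnetic"),
                      replicate = 1L, index = c("AAAA", "CCCC", "GGGG"),
                      stringsAsFactors = FALSE)
  pool <- toy_pool(c("b1", "b2"), c(10, 20), gene_id = c("g1", "g1"),
                   central = TRUE)
  counts <- matrix(c(2L, 50L,  10L, 40L,  10L, 40L), nrow = 2,
                   dimnames = list(pool$barcode, sheet$sampleId))
  cm <- magscreen:::new_count_matrix(counts, setNames(integer(3), sheet$sampleId), sheet)
  # b1 has 2 t0 reads < 3 -> only b2 scores; gene score is b2's strain score
  sc <- score_genes(cm, pool, config = score_config(t0_min_reads = 3))
  mag <- sc$raw[sc$raw$fraction == "magnetic", ]
  expect_equal(mag$n_strains, 1L)
  expect_equal(mag$score,
               strain_score(40, 50, sum(counts[, 3]), sum(counts[, 1])))
  # requiring 2 strains omits the gene entirely (not scored 0)
  expect_error(score_genes(cm, pool, config = score_config(t0_min_reads = 3,
                                                           min_strains_per_gene = 2)))
})
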