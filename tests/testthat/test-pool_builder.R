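test_that("parse_tnseq_read extracts barcode and junction and enumerates rejections", {
  md <- tnseq_model()
  bc <- strrep("A", 20)
  junc <- strrep("G", 20)
  ok <- parse_tnseq_read(paste0(md$flank5, bc, md$flank3, junc), md)
  expect_equal(ok$status, "ok")
  expect_equal(ok$barcode, bc)
  expect_equal(ok$junction, junc)

  cases <- list(
    flank5_missing = paste0("TTTT", bc, md$flank3, junc),
    flank3_missing = paste0(md$flank5, bc, "TTTTTTTTTTTTTTTTTT", junc),
    barcode_N = paste0(md$flank5, strrep("A", 19), "N", md$flank3, junc),
    junction_short = paste0(md$flank5, bc, md$flank3, "ACGT"))
  for (reason in names(cases)) {
    r <- parse_tnseq_read(cases[[reason]], md)
    expect_equal(r$status, "reject")
    expect_equal(r$reason, reason)
  }
})

test_that("map_junction frozen examples", {
  g <- data.frame(scaffold_id = "s1", sequence = "AAAACCCCGGGGTTTT",
                  length = 16L, stringsAsFactors = FALSE)
  m <- map_junction("CCCCGGGG", g)
  expect_equal(m[c("status", "position", "strand")],
               list(status = "mapped", position = 5L, strand = "+"))
  g2 <- data.frame(scaffold_id = "s1", sequence = "ACGTACGTAC", length = 10L)
  expect_equal(map_junction("GTAC", g2)$status, "multimapped")
  g3 <- toy_genome(len = 300, seed = 1)
  g3$sequence <- gsub("AAAA", "ACGT", g3$sequence)  # ensure no 8-A run
  expect_equal(map_junction(strrep("A", 8), g3)$status, "unmapped")
  expect_error(map_junction("", g), "empty")
})

test_that("map_junction agrees with a brute-force scan oracle", {
  set.seed(23)
  g <- toy_genome(len = 3000, seed = 23)
  pos <- sample(2900, 30)
  juncs <- c(
    substring(g$sequence, pos, pos + 17),
    vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                                   collapse = ""), ""))
  for (j in unique(juncs)) {
    hits <- oracle_scan(j, g)
    m <- map_junction(j, g)
    expect_equal(m$status, switch(as.character(min(nrow(hits), 2L)),
                                  "0" = "unmapped", "1" = "mapped",
                                  "2" = "multimapped"))
    if (m$status == "mapped") {
      expect_equal(m$position, hits$pos)
      expect_equal(m$strand, hits$strand)
    }
  }
})

test_that("build_pool keeps modal loci and applies the chimeric fraction rule", {
  g <- toy_genome(len = 5000, seed = 42)
  md <- tnseq_model()
  genes <- toy_genes(401, 800)
  b1 <- strrep("A", 20); b2 <- strrep("C", 20); b3 <- strrep("G", 20)
  reads <- c(
    rep(toy_tnseq_read(g, b1, 501), 10),              # clean, central in g01
    rep(toy_tnseq_read(g, b2, 501), 3),               # same position, own row
    rep(toy_tnseq_read(g, b3, 601), 6),               # chimeric: 6 vs 4
    rep(toy_tnseq_read(g, b3, 2001), 4))
  pool <- build_pool(reads, md, g, genes)
  expect_equal(nrow(pool), 3L)
  r1 <- pool[pool$barcode == b1, ]
  expect_equal(r1$pos, 501L)
  expect_equal(r1$n_reads, 10L)
  expect_true(r1$central)
  expect_equal(r1$gene_id, "g01")
  expect_false(r1$multimapped)
  expect_equal(pool$pos[pool$barcode == b2], 501L)    # barcode-keyed, not position-keyed
  r3 <- pool[pool$barcode == b3, ]
  expect_true(r3$multimapped)                          # minority 4/10 > 0.25
  expect_equal(r3$pos, 601L)

  expect_error(build_pool(c("TTTT", "GGGG"), md, g), "usable")
})

test_that("build_pool minority fraction boundary and strandedness", {
  g <- toy_genome(len = 5000, seed = 5)
  md <- tnseq_model()
  b <- strrep("T", 20)
  # 8 vs 2: minority 0.2 <= 0.25, not flagged
  reads <- c(rep(toy_tnseq_read(g, b, 901), 8), rep(toy_tnseq_read(g, b, 3001), 2))
  pool <- build_pool(reads, md, g)
  expect_false(pool$multimapped)
  expect_equal(pool$n_reads, 8L)
  # minus-strand junction maps back to the same forward-strand position
  rneg <- toy_tnseq_read(g, strrep("A", 20), 1201, strand = "-")
  pneg <- build_pool(rep(rneg, 4), md, g)
  expect_equal(pneg$pos, 1201L)
  expect_equal(pneg$strand, "-")
})

test_that("assign_genes flags ambiguous overlaps and non-central gene bodies", {
  genes <- toy_genes(c(101, 301), c(400, 600))  # overlap 301..400
  pool <- toy_pool(c("b1", "b2", "b3", "b4"), c(350, 150, 110, 50))
  pool <- assign_genes(pool, genes)
  # 350 is central to both genes -> ambiguous, excluded
  expect_true(is.na(pool$gene_id[1]) && !pool$central[1])
  # 150 central to g01 only
  expect_equal(pool$gene_id[2], "g01")
  expect_true(pool$central[2])
  # 110 in g01 body but before its central region start (101+30=131)
  expect_equal(pool$gene_id[3], "g01")
  expect_false(pool$central[3])
  # intergenic
  expect_true(is.na(pool$gene_id[4]))
})

test_that("pool_qc computes the stated statistics", {
  genes <- toy_genes(c(1, 1001, 2001), c(900, 1900, 2900))
  # central strain counts 2, 3, 7 across the genes
  mk <- function(gene, n, reads) {
    toy_pool(paste0(gene, "_", seq_len(n)), 100, gene_id = gene,
             central = TRUE, n_reads = reads)
  }
  pool <- rbind(mk("g01", 2, 5), mk("g02", 3, 5), mk("g03", 7, 5))
  qc <- pool_qc(pool, genes)
  expect_equal(qc$hits_per_protein_mean, 4.0)
  expect_equal(qc$hits_per_protein_median, 3)
  expect_equal(qc$n_unique_barcodes, 12L)

  # reads per hit protein 10, 10, 20, 40 -> mean 20, median 15, bias 5
  genes4 <- toy_genes(seq(1, 3001, by = 1000), seq(900, 3901, by = 1000))
  pool4 <- rbind(mk("g01", 1, 10), mk("g02", 1, 10), mk("g03", 1, 20),
                 mk("g04", 1, 40))
  qc4 <- pool_qc(pool4, genes4)
  expect_equal(qc4$reads_per_hit_protein_mean, 20)
  expect_equal(qc4$reads_per_hit_protein_median, 15)
  expect_equal(qc4$read_bias, 5.0)

  # identical read totals -> zero bias
  pool0 <- rbind(mk("g01", 2, 10), mk("g02", 2, 10))
  expect_equal(pool_qc(pool0, genes4)$read_bias, 0)

  expect_error(pool_qc(toy_pool("b1", 10), genes), "hit proteins")
})

test_that("pool TSV round trip is exact including NA gene ids", {
  pool <- toy_pool(c("b1", "b2"), c(10, 20), gene_id = c("g01", NA),
                   central = c(TRUE, FALSE), n_reads = c(3, 8),
                   multimapped = c(FALSE, TRUE))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(pool, p)
  expect_identical(read_pool_tsv(p), pool)
})

test_that("pool loci re-checked against the genome by brute force all match", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  idx <- sample(nrow(ps$pool), 40)
  for (i in idx) {
    junc <- substring(sim$genome$sequence, ps$pool$pos[i],
                      ps$pool$pos[i] + cfg$junction_len - 1L)
    hits <- oracle_scan(junc, sim$genome)
    expect_true(ps$pool$pos[i] %in% hits$pos)
  }
})
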