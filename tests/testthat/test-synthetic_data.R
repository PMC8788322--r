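test_that("simulate_genome is deterministic, disjoint, and respects the rounding rule", {
  cfg <- small_sim_config(seed = 1)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)
  expect_equal(length(a$truth$essential), floor(cfg$n_genes * cfg$essential_fraction))
  # effect genes never essential
  expect_length(intersect(a$truth$effects$gene_id, a$truth$essential), 0)
  # genes non-overlapping and inside the scaffold
  g <- a$genes
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(all(g$end <= a$genome$length) && all(g$start >= 1))
  # no essentials when the fraction is zero
  cfg0 <- small_sim_config(seed = 2, essential_fraction = 0)
  expect_length(simulate_genome(cfg0)$truth$essential, 0)
  # over-dense placement errors
  expect_error(simulate_genome(sim_config(seed = 1, genome_len = 10000L,
                                          n_genes = 50L, mai_block = NULL)),
               "dense")
})

test_that("simulate_pool discards lethal insertions and yields unique barcodes", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  expect_false(anyDuplicated(ps$pool$barcode) > 0)
  expect_true(all(nchar(ps$pool$barcode) == 20L))
  cen <- ps$pool[ps$pool$central & !is.na(ps$pool$gene_id), ]
  # planted essentials have zero central strains by construction
  expect_length(intersect(unique(cen$gene_id), sim$truth$essential), 0)
  # realized strains per nonessential gene near the configured target
  tab <- table(factor(cen$gene_id, levels = sim$genes$gene_id))
  noness <- setdiff(sim$genes$gene_id, sim$truth$essential)
  target <- cfg$n_insertions * 0.8 * mean(sim$genes$length) / cfg$genome_len
  expect_lt(abs(mean(tab[noness]) - target) / target, 0.2)
})

test_that("selection conserves cells strain by strain and is seed-deterministic", {
  cfg <- small_sim_config(seed = 4)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  sel1 <- simulate_selection(ps, sim$truth, cfg)
  sel2 <- simulate_selection(ps, sim$truth, cfg)
  expect_identical(sel1$counts$counts, sel2$counts$counts)
  for (r in seq_len(cfg$replicates)) {
    cells <- sel1$cells[[r]]
    expect_identical(cells$magnetic + cells$nonmagnetic, cells$precolumn)
    expect_equal(sum(cells$precolumn), cfg$cell_depth)
  }
  # read depth honored
  expect_true(all(colSums(sel1$counts$counts) == cfg$read_depth))
})

test_that("null selection gives expected MCS 0; planted defect matches log2(p/p_wt)", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  sel <- simulate_selection(ps, sim$truth, cfg)
  sc <- score_genes(sel$counts, ps$pool)
  mm <- replicate_mean(sc$norm, fraction = "magnetic")
  eff <- sim$truth$effects
  for (i in seq_len(nrow(eff))) {
    est <- mm$mean_mcs[mm$gene_id == eff$gene_id[i]]
    expect_lt(abs(est - eff$expected_mcs[i]), 0.35)
  }
  null_mcs <- mm$mean_mcs[!mm$gene_id %in% eff$gene_id]
  expect_lt(abs(median(null_mcs)), 0.05)
})

test_that("TnSeq FASTQ emission round-trips through build_pool", {
  cfg <- small_sim_config(seed = 6)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_tnseq_fastq(ps, sim$genome, cfg, fq)
  pool2 <- build_pool(fq, tnseq_model(), sim$genome, sim$genes)
  expect_equal(nrow(pool2), nrow(ps$pool))
  m <- merge(ps$pool, pool2, by = "barcode")
  expect_equal(nrow(m), nrow(ps$pool))
  expect_true(all(m$pos.x == m$pos.y & m$strand.x == m$strand.y))
  expect_true(all(m$n_reads.x == m$n_reads.y))
  expect_identical(m$central.x, m$central.y)
  # byte-determinism of emission under the same seed
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  emit_tnseq_fastq(ps, sim$genome, cfg, fq2)
  expect_identical(readLines(fq), readLines(fq2))
})

test_that("BarSeq FASTQ emission reproduces counts exactly, off-pool reads tallied", {
  cfg <- small_sim_config(seed = 7)
  sheet <- data.frame(sampleId = c("std_t0_r1", "std_precolumn_r1"),
                      condition = "std", fraction = c("t0", "precolumn"),
                      replicate = 1L, index = c("AACCGGTT", "ACACACAC"),
                      stringsAsFactors = FALSE)
  pool <- toy_pool(c(strrep("A", 20), strrep("C", 20), strrep("G", 20)),
                   c(100, 200, 300))
  counts <- matrix(c(5L, 2L, 0L, 1L, 4L, 9L), nrow = 3,
                   dimnames = list(pool$barcode, sheet$sampleId))
  cm <- magscreen:::new_count_matrix(counts, setNames(integer(2), sheet$sampleId), sheet)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_barseq_fastq(cm, cfg, fq, n_offpool = 4L)
  back <- count_barcodes(fq, barseq_model(), sheet, pool)
  expect_identical(back$counts, counts)
  expect_true(all(back$unknown == 4L))
})

test_that("read errors reduce barcode recovery as expected", {
  cfg <- small_sim_config(seed = 9, error_rate = 0.01)
  sim <- simulate_genome(cfg)
  ps <- simulate_pool(sim, cfg)
  # subsample strains to keep the corrupting loop cheap
  ps$strains <- ps$strains[1:200, ]
  ps$pool <- ps$pool[1:200, ]
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_tnseq_fastq(ps, sim$genome, cfg, fq)
  pool2 <- suppressWarnings(build_pool(fq, tnseq_model(), sim$genome))
  rec <- mean(ps$pool$barcode %in% pool2$barcode)
  expect_lt(rec, 1)
  # expected per-read barcode survival (1 - e)^20 ~ 0.82; with ~11 reads per
  # strain nearly every barcode should still be seen at least once
  expect_gt(rec, 0.9)
})

test_that("simulate_screen writes a consistent artifact set", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 10)
  out <- simulate_screen(cfg, dir)
  genome <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(genome, out$sim$genome)
  genes <- read_gff(file.path(dir, "genes.gff3"), genome = genome)
  expect_identical(genes, out$sim$genes[order(out$sim$genes$start), ])
  pool <- read_pool_tsv(file.path(dir, "pool.tsv"))
  expect_identical(pool, out$pool_sim$pool)
  cm <- read_counts_tsv(file.path(dir, "counts.tsv"),
                        read_sample_sheet(file.path(dir, "samples.tsv")))
  expect_identical(cm$counts, out$selection$counts$counts)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(truth$geneId[truth$role == "essential"], out$sim$truth$essential)
})

test_that("CLI dispatches the simulate and essentials subcommands", {
  dir <- withr::local_tempdir()
  # the CLI runs the full default-scale simulator; keep to one invocation
  expect_output(magscreen_cli(c("simulate", "--seed", "5", "--out", dir)),
                "simulated screen")
  out_tsv <- file.path(dir, "ess.tsv")
  expect_output(
    magscreen_cli(c("essentials", "--pool", file.path(dir, "pool.tsv"),
                    "--genes", file.path(dir, "genes.gff3"),
                    "--out", out_tsv)),
    "Essentiality calls")
  calls <- utils::read.delim(out_tsv)
  expect_equal(nrow(calls), 200L)
  expect_equal(sum(calls$class == "essential"), 20L)
})
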