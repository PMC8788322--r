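# Forward simulator of a barcoded transposon screen with magnetic-column
# selection. The stated world: ~10% essential genes, ~34 insertion strains
# per gene, 20-nt random barcodes, 3 biological replicates, four fractions
# (t0, precolumn, magnetic, nonmagnetic). Column retention is per-cell
# Bernoulli with a gene-level probability p_g (wild type p_wt), giving the
# closed-form expected magnetic MCS log2(p_g / p_wt).

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a real RB-TnSeq screen:
#' 200 genes on a 200 kb scaffold, lognormal gene lengths with median
#' ~900 nt, 10% essential genes, enough insertions for ~34 surviving
#' central strains per nonessential gene, and a magnetosome-island-like
#' block of genes whose mutants are poorly retained on the column
#' (retention 0.25 vs wild-type 0.9) plus one gene whose mutants are
#' retained better than wild type (0.99), emulating an enrichment hit.
#'
#' @param seed Integer seed; all simulator stages derive their RNG state
#'   from it (mandatory for reproducibility).
#' @param genome_len Scaffold length in nt.
#' @param n_genes Number of genes.
#' @param gene_len_meanlog,gene_len_sdlog Lognormal gene-length parameters
#'   (median `exp(meanlog)` ~ 900 nt).
#' @param essential_fraction Fraction of genes planted essential
#'   (`floor(n_genes * essential_fraction)` genes).
#' @param mai_block Data.frame with columns `gene_index`, `p`: per-gene
#'   column retention probabilities for effect genes. `NULL` disables
#'   effects (all wild type).
#' @param p_wt Wild-type column retention probability.
#' @param n_insertions Transposon insertions attempted (default 9200,
#'   sized for ~34 central strains per nonessential gene).
#' @param growth_fitness Optional named vector (gene_id -> multiplier)
#'   applied to strain abundance during the growth phase.
#' @param read_depth Reads per BarSeq sample.
#' @param cell_depth Cells loaded per replicate column.
#' @param replicates Biological replicates per condition.
#' @param condition Condition label for the sample sheet.
#' @param tn_reads_mean Mean TnSeq reads per strain.
#' @param strain_bias_sdlog Lognormal sd of per-strain library abundance
#'   (gives the mild mean-vs-median read bias seen in real libraries).
#' @param junction_len Genomic junction length in emitted TnSeq reads.
#' @param error_rate Per-base substitution rate in emitted FASTQ (0 = off;
#'   all default analyses are error-free).
#' @param lo_frac,hi_frac Central-region fractions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_len = 200000L, n_genes = 200L,
                       gene_len_meanlog = log(900), gene_len_sdlog = 0.25,
                       essential_fraction = 0.10,
                       mai_block = default_mai_block(),
                       p_wt = 0.9, n_insertions = 9200L,
                       growth_fitness = NULL,
                       read_depth = 300000L, cell_depth = 1000000L,
                       replicates = 3L, condition = "standard",
                       tn_reads_mean = 10, strain_bias_sdlog = 0.35,
                       junction_len = 20L, error_rate = 0,
                       lo_frac = 0.1, hi_frac = 0.9) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(p_wt > 0, p_wt <= 1, n_insertions > 0, replicates >= 1,
            essential_fraction >= 0, essential_fraction < 1,
            error_rate >= 0, error_rate < 1)
  if (!is.null(mai_block)) {
    stopifnot(is.data.frame(mai_block),
              all(c("gene_index", "p") %in% names(mai_block)),
              all(mai_block$p > 0), all(mai_block$p <= 1),
              all(mai_block$gene_index >= 1), all(mai_block$gene_index <= n_genes))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default effect-gene block
#'
#' Twelve contiguous genes with column retention 0.25 (a magnetosome-island
#' analogue whose mutants are depleted from the magnetic fraction) and one
#' distal gene with retention 0.99 (mutants enriched relative to wild type).
#'
#' @return Data.frame with columns `gene_index`, `p`.
#' @export
default_mai_block <- function() {
  data.frame(gene_index = c(101:112, 150L),
             p = c(rep(0.25, 12L), 0.99))
}

# Deterministic child seed for a simulator stage.
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2000000011L

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a genome, gene annotations, and screen ground truth
#'
#' Places non-overlapping genes sequentially on one scaffold (both strands,
#' lognormal lengths), samples essential genes disjointly from the effect
#' block, and records per-gene retention probabilities with their analytic
#' expected magnetic MCS `log2(p_g / p_wt)`.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (as [read_fasta()]), `genes` (as
#'   [read_gff()]), and `truth` (list: `essential` gene ids, `effects`
#'   data.frame `gene_id`, `p`, `expected_mcs`, `expected_sign`; `p_wt`).
#' @export
simulate_genome <- function(config) {
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_genes
  lens <- pmax(60L, as.integer(round(stats::rlnorm(
    n, config$gene_len_meanlog, config$gene_len_sdlog))))
  min_gap <- 20L
  spare <- config$genome_len - sum(lens) - (n + 1L) * min_gap
  if (spare < 0) stop("genes cannot be placed: genome too dense")
  extra <- stats::rmultinom(1L, spare, rep(1, n + 1L))[, 1L]
  gaps <- min_gap + extra
  starts <- cumsum(c(gaps[1L] + 1L, lens[-n] + gaps[-1L][-n]))
  ends <- starts + lens - 1L
  stopifnot(ends[n] <= config$genome_len)
  gene_id <- sprintf("MAG_RS%05d", seq_len(n) * 5L)
  aliases <- sprintf("mag%04d", seq_len(n))
  effects <- config$mai_block
  eff_idx <- if (is.null(effects)) integer() else as.integer(effects$gene_index)
  n_ess <- floor(n * config$essential_fraction)
  candidates <- setdiff(seq_len(n), eff_idx)
  if (n_ess > length(candidates)) stop("not enough non-effect genes to plant essentials")
  ess_idx <- sort(sample(candidates, n_ess))
  product <- rep("hypothetical protein", n)
  product[eff_idx] <- "magnetosome formation protein"
  genes <- data.frame(gene_id = gene_id, aliases = aliases,
                      scaffold_id = "scaffold1", start = starts, end = ends,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      product = product, length = lens,
                      stringsAsFactors = FALSE)
  genome <- data.frame(
    scaffold_id = "scaffold1",
    sequence = paste(sample(c("A", "C", "G", "T"), config$genome_len,
                            replace = TRUE), collapse = ""),
    length = config$genome_len, stringsAsFactors = FALSE)
  truth <- list(essential = gene_id[ess_idx], p_wt = config$p_wt)
  if (length(eff_idx)) {
    truth$effects <- data.frame(
      gene_id = gene_id[eff_idx], p = effects$p,
      expected_mcs = log2(effects$p / config$p_wt),
      expected_sign = ifelse(effects$p < config$p_wt, "-",
                             ifelse(effects$p > config$p_wt, "+", "0")),
      stringsAsFactors = FALSE)
  } else {
    truth$effects <- data.frame(gene_id = character(), p = numeric(),
                                expected_mcs = numeric(),
                                expected_sign = character(),
                                stringsAsFactors = FALSE)
  }
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate the transposon insertion pool
#'
#' Insertion positions are uniform over the scaffold (kept clear of the
#' last `junction_len` bases so junction reads never run off the end).
#' Insertions landing in the central region of a planted essential gene are
#' lethal and discarded. Each surviving insertion becomes a strain with a
#' unique random 20-nt barcode, a lognormal initial library abundance, and
#' a TnSeq read count `1 + Poisson(tn_reads_mean * bias)`.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `pool` (schema of [build_pool()]) and `strains`
#'   (adds `abundance0`, the latent initial abundance).
#' @export
simulate_pool <- function(sim, config) {
  set.seed(stage_seed(config$seed, 2L))
  genes <- sim$genes
  max_pos <- config$genome_len - config$junction_len + 1L
  pos <- sample.int(max_pos, config$n_insertions, replace = TRUE)
  strand <- sample(c("+", "-"), config$n_insertions, replace = TRUE)
  cr <- central_region(genes$start, genes$end, config$lo_frac, config$hi_frac)
  ess <- genes$gene_id %in% sim$truth$essential
  lethal <- rep(FALSE, length(pos))
  for (g in which(ess)) {
    lethal <- lethal | (pos >= cr$lo[g] & pos <= cr$hi[g])
  }
  pos <- pos[!lethal]; strand <- strand[!lethal]
  n <- length(pos)
  if (n == 0L) stop("no surviving insertions")
  barcodes <- random_dna(n, 20L)
  while (anyDuplicated(barcodes)) {
    dup <- which(duplicated(barcodes))
    barcodes[dup] <- random_dna(length(dup), 20L)
  }
  bias <- stats::rlnorm(n, 0, config$strain_bias_sdlog)
  n_reads <- 1L + stats::rpois(n, config$tn_reads_mean * bias)
  pool <- data.frame(barcode = barcodes, scaffold = "scaffold1", pos = pos,
                     strand = strand, n_reads = n_reads,
                     gene_id = NA_character_, central = FALSE,
                     multimapped = FALSE, stringsAsFactors = FALSE)
  pool <- assign_genes(pool, genes, config$lo_frac, config$hi_frac)
  abundance0 <- stats::rlnorm(n, 0, config$strain_bias_sdlog)
  strains <- cbind(pool, data.frame(abundance0 = abundance0))
  list(pool = pool, strains = strains)
}

#' Simulate growth and magnetic-column selection
#'
#' Per replicate: time-zero reads are a multinomial draw from the initial
#' strain abundances; the grown culture (abundance x growth fitness) is
#' realized as `cell_depth` precolumn cells (multinomial); each cell is
#' retained on the column with its strain's gene-level probability
#' (binomial), the flowthrough being the complement, so
#' magnetic + nonmagnetic cells = precolumn cells strain by strain; reads
#' for each fraction are multinomial draws from the corresponding cell
#' proportions at `read_depth`.
#'
#' @param pool_sim Output of [simulate_pool()].
#' @param truth Truth list from [simulate_genome()].
#' @param config The [sim_config()].
#' @return A list with `counts` (a `count_matrix` including the sample
#'   sheet), `sheet`, and `cells` (list per replicate of the latent
#'   strain x {precolumn, magnetic, nonmagnetic} cell counts).
#' @export
simulate_selection <- function(pool_sim, truth, config) {
  set.seed(stage_seed(config$seed, 3L))
  strains <- pool_sim$strains
  n <- nrow(strains)
  p_strain <- rep(truth$p_wt, n)
  if (nrow(truth$effects)) {
    m <- match(strains$gene_id, truth$effects$gene_id)
    hit <- !is.na(m) & strains$central & !strains$multimapped
    p_strain[hit] <- truth$effects$p[m[hit]]
  }
  w <- rep(1, n)
  if (!is.null(config$growth_fitness)) {
    m <- match(strains$gene_id, names(config$growth_fitness))
    hit <- !is.na(m) & strains$central
    w[hit] <- config$growth_fitness[m[hit]]
  }
  fractions <- c("t0", "precolumn", "magnetic", "nonmagnetic")
  reps <- seq_len(config$replicates)
  sheet <- expand.grid(fraction = fractions, replicate = reps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- data.frame(
    sampleId = paste0(config$condition, "_", sheet$fraction, "_r", sheet$replicate),
    condition = config$condition, fraction = sheet$fraction,
    replicate = sheet$replicate,
    index = make_indices(nrow(sheet)), stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  counts <- matrix(0L, nrow = n, ncol = nrow(sheet),
                   dimnames = list(strains$barcode, sheet$sampleId))
  cells <- vector("list", config$replicates)
  draw_reads <- function(weights) {
    if (sum(weights) <= 0) return(integer(n))
    stats::rmultinom(1L, config$read_depth, weights)[, 1L]
  }
  for (r in reps) {
    t0_id <- sheet$sampleId[sheet$fraction == "t0" & sheet$replicate == r]
    pre_id <- sheet$sampleId[sheet$fraction == "precolumn" & sheet$replicate == r]
    mag_id <- sheet$sampleId[sheet$fraction == "magnetic" & sheet$replicate == r]
    non_id <- sheet$sampleId[sheet$fraction == "nonmagnetic" & sheet$replicate == r]
    counts[, t0_id] <- draw_reads(strains$abundance0)
    pre_cells <- stats::rmultinom(1L, config$cell_depth,
                                  strains$abundance0 * w)[, 1L]
    mag_cells <- stats::rbinom(n, pre_cells, p_strain)
    non_cells <- pre_cells - mag_cells
    counts[, pre_id] <- draw_reads(pre_cells)
    counts[, mag_id] <- draw_reads(mag_cells)
    counts[, non_id] <- draw_reads(non_cells)
    cells[[r]] <- data.frame(barcode = strains$barcode,
                             precolumn = pre_cells, magnetic = mag_cells,
                             nonmagnetic = non_cells, stringsAsFactors = FALSE)
  }
  cm <- new_count_matrix(counts,
                         stats::setNames(integer(nrow(sheet)), sheet$sampleId),
                         sheet)
  list(counts = cm, sheet = sheet, cells = cells)
}

# Deterministic unique index sequences (8 nt) for the sample sheet.
make_indices <- function(k) {
  alpha <- c("A", "C", "G", "T")
  vapply(seq_len(k), function(i) {
    d <- integer(8L); x <- i + 7L  # offset so index 1 is not all-A
    for (j in 1:8) { d[j] <- x %% 4L; x <- x %/% 4L }
    paste(alpha[d + 1L], collapse = "")
  }, "")
}

#' Emit TnSeq FASTQ reads for a simulated pool
#'
#' Each strain yields `n_reads` identical (error-free) reads assembled as
#' `flank5 + barcode + flank3 + junction`, where the junction is the
#' genomic sequence at the insertion locus (reverse-complemented for
#' minus-strand insertions). An optional per-base substitution rate
#' corrupts reads for recovery experiments.
#'
#' @param pool_sim Output of [simulate_pool()].
#' @param genome Genome table from [simulate_genome()].
#' @param config The [sim_config()].
#' @param path Output FASTQ path.
#' @param model A [tnseq_model()] (defaults match the parser defaults).
#' @return `path`, invisibly.
#' @export
emit_tnseq_fastq <- function(pool_sim, genome, config, path,
                             model = tnseq_model()) {
  set.seed(stage_seed(config$seed, 4L))
  strains <- pool_sim$strains
  jl <- config$junction_len
  junc <- substring(genome$sequence, strains$pos, strains$pos + jl - 1L)
  neg <- strains$strand == "-"
  if (any(neg)) {
    junc[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(junc[neg])))
  }
  reads <- paste0(model$flank5, strains$barcode, model$flank3, junc)
  reads <- rep(reads, strains$n_reads)
  reads <- reads[sample.int(length(reads))]
  if (config$error_rate > 0) reads <- corrupt_reads(reads, config$error_rate)
  write_fastq(reads, path, prefix = "tn")
  invisible(path)
}

#' Emit BarSeq FASTQ reads from a count matrix
#'
#' Each count becomes that many reads `index + flank + barcode`. Optional
#' off-pool reads (random barcodes absent from the pool) exercise the
#' unknown-barcode tally.
#'
#' @param cm A `count_matrix` (e.g. from [simulate_selection()]).
#' @param config The [sim_config()].
#' @param path Output FASTQ path.
#' @param model A [barseq_model()].
#' @param n_offpool Off-pool reads to plant per sample (default 0).
#' @return `path`, invisibly.
#' @export
emit_barseq_fastq <- function(cm, config, path, model = barseq_model(),
                              n_offpool = 0L) {
  set.seed(stage_seed(config$seed, 5L))
  sheet <- cm$sheet
  all_reads <- character()
  for (j in seq_len(ncol(cm$counts))) {
    idx <- sheet$index[match(colnames(cm$counts)[j], sheet$sampleId)]
    cnt <- cm$counts[, j]
    nz <- cnt > 0L
    reads <- rep(paste0(idx, model$flank5, rownames(cm$counts)[nz]), cnt[nz])
    if (n_offpool > 0L) {
      off <- random_dna(n_offpool, model$barcode_len)
      off <- setdiff(off, rownames(cm$counts))
      reads <- c(reads, paste0(idx, model$flank5, off))
    }
    all_reads <- c(all_reads, reads)
  }
  all_reads <- all_reads[sample.int(length(all_reads))]
  if (config$error_rate > 0) all_reads <- corrupt_reads(all_reads, config$error_rate)
  write_fastq(all_reads, path, prefix = "bs")
  invisible(path)
}

# Substitute bases uniformly at rate e (N never introduced).
corrupt_reads <- function(reads, e) {
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < e)
    if (!length(hit)) return(r)
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

write_fastq <- function(reads, path, prefix = "r") {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", prefix, seq_along(reads)),
                           reads, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full simulator and write all artifacts
#'
#' Convenience wrapper: genome FASTA, genes GFF3, pool TSV, truth TSV,
#' sample sheet TSV, counts TSV, and (optionally) TnSeq/BarSeq FASTQ.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param fastq Also emit FASTQ files (default FALSE; the BarSeq file is
#'   large at default depths).
#' @return Invisibly, the list of simulated objects.
#' @export
simulate_screen <- function(config, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  ps <- simulate_pool(sim, config)
  sel <- simulate_selection(ps, sim$truth, config)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gff(sim$genes, file.path(dir, "genes.gff3"))
  write_pool_tsv(ps$pool, file.path(dir, "pool.tsv"))
  write_sample_sheet(sel$sheet, file.path(dir, "samples.tsv"))
  write_counts_tsv(sel$counts, file.path(dir, "counts.tsv"))
  tr <- sim$truth
  truth_df <- data.frame(geneId = c(tr$essential, tr$effects$gene_id),
                         role = c(rep("essential", length(tr$essential)),
                                  rep("effect", nrow(tr$effects))),
                         p = c(rep(NA_real_, length(tr$essential)), tr$effects$p),
                         expectedMCS = c(rep(NA_real_, length(tr$essential)),
                                         tr$effects$expected_mcs))
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (fastq) {
    emit_tnseq_fastq(ps, sim$genome, config, file.path(dir, "tnseq.fastq"))
    emit_barseq_fastq(sel$counts, config, file.path(dir, "barseq.fastq"))
  }
  invisible(list(sim = sim, pool_sim = ps, selection = sel))
}
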