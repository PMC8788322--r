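# Shared fixture builders. Everything is generated in code; no data files.

# A one-scaffold genome with a given (or random) sequence.
toy_genome <- function(sequence = NULL, len = 5000L, seed = 42L) {
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }
  data.frame(scaffold_id = "s1", sequence = sequence,
             length = nchar(sequence), stringsAsFactors = FALSE)
}

# A gene table from start/end vectors.
toy_genes <- function(start, end, strand = NULL, scaffold = "s1") {
  n <- length(start)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             aliases = sprintf("old%02d", seq_len(n)),
             scaffold_id = scaffold, start = as.integer(start),
             end = as.integer(end),
             strand = if (is.null(strand)) rep("+", n) else strand,
             product = "hypothetical protein",
             length = as.integer(end - start + 1L), stringsAsFactors = FALSE)
}

# A pool row builder for hand-made pools.
toy_pool <- function(barcode, pos, gene_id = NA_character_, central = FALSE,
                     n_reads = 1L, multimapped = FALSE, strand = "+",
                     scaffold = "s1") {
  data.frame(barcode = barcode, scaffold = scaffold, pos = as.integer(pos),
             strand = strand, n_reads = as.integer(n_reads),
             gene_id = gene_id, central = central, multimapped = multimapped,
             stringsAsFactors = FALSE)
}

# Assemble a TnSeq read for a given barcode and genomic position.
toy_tnseq_read <- function(genome, barcode, pos, jlen = 20L,
                           model = tnseq_model(), strand = "+") {
  junc <- substring(genome$sequence, pos, pos + jlen - 1L)
  if (strand == "-") {
    junc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(junc)))
  }
  paste0(model$flank5, barcode, model$flank3, junc)
}

# Scaled-down simulation config for fast tests: ~33 central strains per
# nonessential gene at 1/5 the default genome size.
small_sim_config <- function(seed,
                             mai_block = data.frame(gene_index = c(20L, 21L, 35L),
                                                    p = c(0.25, 0.45, 0.99)),
                             ...) {
  sim_config(seed = seed, genome_len = 40000L, n_genes = 40L,
             n_insertions = 1800L, read_depth = 60000L, cell_depth = 200000L,
             mai_block = mai_block, ...)
}

# Brute-force occurrence scan (independent oracle for junction mapping):
# plain-text search of the junction and its reverse complement.
oracle_scan <- function(junction, genome) {
  stopifnot(nchar(junction) > 0)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(junction)))
  hits <- data.frame(scaffold = character(), pos = integer(),
                     strand = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genome))) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") junction else rc
      if (str == "-" && rc == junction) next
      # step through match-by-match so overlapping occurrences are counted
      starts <- integer(); from <- 1L
      repeat {
        hit <- regexpr(pat, substring(genome$sequence[i], from), fixed = TRUE)
        if (hit < 0L) break
        starts <- c(starts, from + hit - 1L)
        from <- from + hit
      }
      if (length(starts)) {
        hits <- rbind(hits, data.frame(scaffold = genome$scaffold_id[i],
                                       pos = starts, strand = str,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  hits
}
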