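# TnSeq pool construction: barcode/junction extraction from reads,
# exact-match junction mapping, modal-locus resolution per barcode, gene
# assignment, and library QC statistics.

#' TnSeq read model
#'
#' Describes the layout of a TnSeq read:
#' `flank5 | barcode (20 nt) | flank3 | genomic junction`.
#' The flanks are transposon-derived constant sequence; defaults are the
#' arbitrary fixed flanks used by the bundled simulator, so simulated reads
#' parse with a default model. Real data require the model matching the
#' construct actually sequenced.
#'
#' @param flank5 Constant sequence immediately 5' of the barcode.
#' @param flank3 Constant sequence between barcode and genomic junction.
#' @param barcode_len Barcode length in nt (the protocol uses 20).
#' @param min_junction_len Minimum usable junction length in nt.
#' @return A list of class `tnseq_model`.
#' @export
tnseq_model <- function(flank5 = "GATGTCCACGAGGTCTCT",
                        flank3 = "CGTACGCTGCAGGTCGAC",
                        barcode_len = 20L,
                        min_junction_len = 15L) {
  stopifnot(nchar(flank5) > 0, nchar(flank3) > 0,
            barcode_len >= 1, min_junction_len >= 1)
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 barcode_len = as.integer(barcode_len),
                 min_junction_len = as.integer(min_junction_len)),
            class = "tnseq_model")
}

#' Parse one TnSeq read into barcode and junction
#'
#' Locates `flank5`, takes the following `barcode_len` bases as the barcode,
#' requires `flank3` immediately after, and returns the remainder as the
#' genomic junction. Failures are returned as rejections, not errors.
#'
#' @param read A single read sequence (A/C/G/T/N).
#' @param model A [tnseq_model()].
#' @return A list with `status = "ok"` and fields `barcode`, `junction`, or
#'   `status = "reject"` with `reason` in
#'   `flank5_missing`, `flank3_missing`, `barcode_N`, `junction_short`.
#' @export
parse_tnseq_read <- function(read, model = tnseq_model()) {
  p <- parse_tnseq_reads(read, model)
  if (is.na(p$barcode)) list(status = "reject", reason = p$reason)
  else list(status = "ok", barcode = p$barcode, junction = p$junction)
}

# Vectorized TnSeq parser. Returns data.frame(barcode, junction, reason);
# barcode is NA on rejection.
parse_tnseq_reads <- function(reads, model) {
  reads <- toupper(reads)
  n5 <- nchar(model$flank5); n3 <- nchar(model$flank3)
  blen <- model$barcode_len
  pos5 <- as.integer(regexpr(model$flank5, reads, fixed = TRUE))
  bstart <- pos5 + n5
  barcode <- substr(reads, bstart, bstart + blen - 1L)
  f3 <- substr(reads, bstart + blen, bstart + blen + n3 - 1L)
  junction <- substr(reads, bstart + blen + n3, nchar(reads))
  reason <- rep(NA_character_, length(reads))
  bad5 <- pos5 < 0L
  reason[bad5] <- "flank5_missing"
  bad3 <- !bad5 & (f3 != model$flank3)
  reason[bad3] <- "flank3_missing"
  badN <- !bad5 & !bad3 & (nchar(barcode) < blen | grepl("N", barcode, fixed = TRUE))
  reason[badN] <- "barcode_N"
  badJ <- !bad5 & !bad3 & !badN & nchar(junction) < model$min_junction_len
  reason[badJ] <- "junction_short"
  ok <- is.na(reason)
  data.frame(barcode = ifelse(ok, barcode, NA_character_),
             junction = ifelse(ok, junction, NA_character_),
             reason = reason, stringsAsFactors = FALSE)
}

#' Map a genomic junction by exact match
#'
#' Searches the junction and its reverse complement over every scaffold.
#' Exactly one genomic occurrence gives a locus; zero gives `unmapped`,
#' two or more give `multimapped`. The reported position is the first
#' genomic base of the junction on the forward strand; the strand is the
#' strand of the match.
#'
#' @param junction Junction sequence (>= 1 nt; typically >= 15 nt).
#' @param genome Genome table from [read_fasta()].
#' @return A list with `status` in `mapped`, `unmapped`, `multimapped`;
#'   when mapped, also `scaffold`, `position`, `strand`.
#' @export
map_junction <- function(junction, genome) {
  if (is.na(junction) || nchar(junction) == 0L) stop("empty junction")
  junction <- toupper(junction)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(junction)))
  # a palindromic junction matches both strands at the same locus; searching
  # the reverse strand would double-count the identical occurrence
  strands <- if (rc == junction) "+" else c("+", "-")
  hits <- list(); nh <- 0L
  for (i in seq_len(nrow(genome))) {
    subject <- Biostrings::DNAString(genome$sequence[i])
    for (str in strands) {
      pat <- if (str == "+") junction else rc
      m <- Biostrings::matchPattern(pat, subject)
      if (length(m)) {
        for (s in Biostrings::start(m)) {
          nh <- nh + 1L
          hits[[nh]] <- list(scaffold = genome$scaffold_id[i],
                             position = s, strand = str)
        }
      }
    }
    if (nh > 1L) return(list(status = "multimapped"))
  }
  if (nh == 0L) return(list(status = "unmapped"))
  c(list(status = "mapped"), hits[[1L]])
}

# Read sequences from a FASTQ file (plain or gzipped) as a character vector.
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readBStringSet(path, format = "fastq"))
}

# Vectorized exact-match mapping of many junctions (Aho-Corasick via
# matchPDict, grouped by junction width). Same contract per junction as
# map_junction(). Returns data.frame(status, scaffold, pos, strand).
map_junctions <- function(junctions, genome) {
  n <- length(junctions)
  status <- rep("unmapped", n)
  scaf <- rep(NA_character_, n); pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  hits_n <- integer(n)
  subjects <- lapply(genome$sequence, Biostrings::DNAString)
  for (w in unique(nchar(junctions))) {
    gi <- which(nchar(junctions) == w)
    pats <- Biostrings::DNAStringSet(junctions[gi])
    rcs <- Biostrings::reverseComplement(pats)
    # palindromic junctions are searched on the forward strand only (a
    # reverse-strand match would be the same genomic occurrence)
    np <- which(as.character(rcs) != as.character(pats))
    pd_f <- Biostrings::PDict(pats)
    pd_r <- if (length(np)) Biostrings::PDict(rcs[np]) else NULL
    for (s in seq_along(subjects)) {
      for (str in c("+", "-")) {
        if (str == "-" && is.null(pd_r)) next
        m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r, subjects[[s]])
        st <- Biostrings::startIndex(m)
        nh <- lengths(st)
        hit1 <- nh > 0L
        if (!any(hit1)) next
        idx <- if (str == "+") gi[hit1] else gi[np][hit1]
        first_new <- hits_n[idx] == 0L
        scaf[idx[first_new]] <- genome$scaffold_id[s]
        pos[idx[first_new]] <- vapply(st[hit1][first_new], `[`, 0L, 1L)
        strand[idx[first_new]] <- str
        hits_n[idx] <- hits_n[idx] + nh[hit1]
      }
    }
  }
  status[hits_n == 1L] <- "mapped"
  status[hits_n > 1L] <- "multimapped"
  one <- hits_n != 1L
  scaf[one] <- NA_character_; pos[one] <- NA_integer_; strand[one] <- NA_character_
  data.frame(status = status, scaffold = scaf, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}

#' Assign pool rows to genes and flag central insertions
#'
#' An insertion inside the central region (see [central_region()]) of
#' exactly one gene is assigned to it with `central = TRUE`. An insertion
#' central to more than one (overlapping) gene is ambiguous: it gets no
#' gene and is excluded from gene-level analyses. An insertion inside a
#' single gene body but outside its central region is assigned with
#' `central = FALSE`; intergenic insertions get no gene.
#'
#' @param pool Pool table with columns `scaffold`, `pos`.
#' @param genes Gene table from [read_gff()].
#' @param lo_frac,hi_frac Central-region fractions.
#' @return `pool` with `gene_id` and `central` columns (re)filled.
#' @export
assign_genes <- function(pool, genes, lo_frac = 0.1, hi_frac = 0.9) {
  cr <- central_region(genes$start, genes$end, lo_frac, hi_frac)
  gene_id <- rep(NA_character_, nrow(pool))
  central <- rep(FALSE, nrow(pool))
  for (sc in unique(pool$scaffold)) {
    pi <- which(pool$scaffold == sc)
    gi <- which(genes$scaffold_id == sc)
    if (!length(gi)) next
    # central-region membership first, then gene-body membership
    ord <- gi[order(genes$start[gi])]
    pos <- pool$pos[pi]
    n_cent <- integer(length(pi)); cent_gene <- rep(NA_character_, length(pi))
    n_body <- integer(length(pi)); body_gene <- rep(NA_character_, length(pi))
    for (g in ord) {
      inb <- pos >= genes$start[g] & pos <= genes$end[g]
      if (any(inb)) {
        n_body[inb] <- n_body[inb] + 1L
        body_gene[inb] <- genes$gene_id[g]
        inc <- pos >= cr$lo[g] & pos <= cr$hi[g]
        n_cent[inc] <- n_cent[inc] + 1L
        cent_gene[inc] <- genes$gene_id[g]
      }
    }
    take_c <- n_cent == 1L
    gene_id[pi[take_c]] <- cent_gene[take_c]
    central[pi[take_c]] <- TRUE
    take_b <- n_cent == 0L & n_body == 1L
    gene_id[pi[take_b]] <- body_gene[take_b]
  }
  pool$gene_id <- gene_id
  pool$central <- central
  pool
}

#' Build a barcode pool from TnSeq reads
#'
#' Parses reads, maps junctions by exact match, and resolves each barcode
#' to its modal locus. A barcode is flagged `multimapped` when the minority
#' fraction of its uniquely mapped reads exceeds `conflict_frac`, when the
#' modal locus is tied, or when more than `conflict_frac` of its reads have
#' junctions occurring at multiple genomic loci. `n_reads` is the number of
#' reads supporting the modal locus.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param model A [tnseq_model()].
#' @param genome Genome table from [read_fasta()].
#' @param genes Optional gene table; when given, gene assignment and
#'   centrality are computed via [assign_genes()].
#' @param conflict_frac Minority-fraction threshold for flagging chimeric
#'   barcodes (default 0.25).
#' @param lo_frac,hi_frac Central-region fractions passed to [assign_genes()].
#' @return A pool data.frame with columns `barcode`, `scaffold`, `pos`,
#'   `strand`, `n_reads`, `gene_id`, `central`, `multimapped`. Attribute
#'   `stats` holds parse/mapping tallies.
#' @export
build_pool <- function(reads, model = tnseq_model(), genome, genes = NULL,
                       conflict_frac = 0.25, lo_frac = 0.1, hi_frac = 0.9) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq_seqs(reads)
  parsed <- parse_tnseq_reads(reads, model)
  ok <- !is.na(parsed$barcode)
  if (!any(ok)) stop("no usable TnSeq reads (all rejected)")
  bc <- parsed$barcode[ok]
  jn <- parsed$junction[ok]

  uj <- unique(jn)
  loc <- map_junctions(uj, genome)
  ji <- match(jn, uj)
  rd_status <- loc$status[ji]
  rd_key <- ifelse(rd_status == "mapped",
                   paste(loc$scaffold[ji], loc$pos[ji], loc$strand[ji], sep = "\r"),
                   NA_character_)

  # total locus evidence per barcode (mapped + genome-multimapped reads)
  informative <- rd_status != "unmapped"
  tot_tab <- table(bc[informative])
  # per-(barcode, locus) support over uniquely mapped reads
  mp <- rd_status == "mapped"
  if (!any(mp)) stop("no barcodes with a uniquely mapped locus")
  pair <- paste(bc[mp], rd_key[mp], sep = "\x01")
  cnt <- table(pair)
  parts <- strsplit(names(cnt), "\x01", fixed = TRUE)
  pb <- vapply(parts, `[`, "", 1L)
  pk <- vapply(parts, `[`, "", 2L)
  pn <- as.integer(cnt)
  ord <- order(pb, -pn, pk)  # modal locus first; pk breaks order ties stably
  pb <- pb[ord]; pk <- pk[ord]; pn <- pn[ord]
  first <- !duplicated(pb)
  # runner-up support: the count of the second-best locus, 0 if none
  idx_first <- which(first)
  ru <- rep(0L, length(idx_first))
  nxt <- idx_first + 1L
  has_next <- nxt <= length(pb) & c(pb[-1L], "")[idx_first] == pb[idx_first]
  ru[has_next] <- pn[nxt[has_next]]
  modal_b <- pb[first]; modal_key <- pk[first]; modal_n <- pn[first]
  n_tot <- as.integer(tot_tab[modal_b])
  minority <- 1 - modal_n / n_tot
  kp <- strsplit(modal_key, "\r", fixed = TRUE)
  pool <- data.frame(
    barcode = modal_b,
    scaffold = vapply(kp, `[`, "", 1L),
    pos = as.integer(vapply(kp, `[`, "", 2L)),
    strand = vapply(kp, `[`, "", 3L),
    n_reads = modal_n,
    multimapped = (ru == modal_n) | (minority > conflict_frac),
    stringsAsFactors = FALSE)
  pool$gene_id <- NA_character_
  pool$central <- FALSE
  if (!is.null(genes)) pool <- assign_genes(pool, genes, lo_frac, hi_frac)
  pool <- pool[, c("barcode", "scaffold", "pos", "strand", "n_reads",
                   "gene_id", "central", "multimapped")]
  rownames(pool) <- NULL
  rej <- table(parsed$reason[!ok])
  attr(pool, "stats") <- list(
    n_reads_total = length(reads), n_reads_accepted = sum(ok),
    rejections = as.list(rej),
    n_junctions_unmapped = sum(loc$status == "unmapped"),
    n_junctions_multimapped = sum(loc$status == "multimapped"))
  pool
}

#' Library QC statistics
#'
#' Summarizes a barcode pool the way RB-TnSeq libraries are described: a
#' "hit protein" is a gene carrying at least one central, uniquely mapped
#' strain; hits per protein and reads per hit protein are computed over hit
#' proteins, and the read bias is mean minus median reads per hit protein.
#'
#' @param pool Pool table from [build_pool()].
#' @param genes Gene table from [read_gff()].
#' @return A list of class `pool_qc` with fields `n_unique_barcodes`,
#'   `hits_per_protein_mean`, `hits_per_protein_median`,
#'   `reads_per_hit_protein_mean`, `reads_per_hit_protein_median`,
#'   `read_bias`, `fraction_genic`, `fraction_central`, `n_hit_proteins`.
#' @export
pool_qc <- function(pool, genes) {
  if (nrow(pool) == 0L) stop("empty pool")
  cen <- pool[pool$central & !pool$multimapped & !is.na(pool$gene_id), , drop = FALSE]
  if (nrow(cen) == 0L) stop("no hit proteins: pool has no central, uniquely mapped barcodes")
  hits <- table(cen$gene_id)
  reads <- tapply(cen$n_reads, cen$gene_id, sum)
  rb_mean <- mean(reads); rb_median <- stats::median(reads)
  structure(list(
    n_unique_barcodes = nrow(pool),
    n_hit_proteins = length(hits),
    hits_per_protein_mean = mean(as.integer(hits)),
    hits_per_protein_median = stats::median(as.integer(hits)),
    reads_per_hit_protein_mean = rb_mean,
    reads_per_hit_protein_median = rb_median,
    read_bias = rb_mean - rb_median,
    fraction_genic = mean(!is.na(pool$gene_id)),
    fraction_central = mean(pool$central)
  ), class = "pool_qc")
}

#' @export
print.pool_qc <- function(x, ...) {
  cat("Barcode pool QC\n")
  cat(sprintf("  unique barcodes:           %d\n", x$n_unique_barcodes))
  cat(sprintf("  hit proteins:              %d\n", x$n_hit_proteins))
  cat(sprintf("  hits per protein (mean):   %.1f\n", x$hits_per_protein_mean))
  cat(sprintf("  hits per protein (median): %.1f\n", x$hits_per_protein_median))
  cat(sprintf("  read bias (mean-median reads per hit protein): %.2f\n", x$read_bias))
  cat(sprintf("  fraction genic: %.3f  fraction central: %.3f\n",
              x$fraction_genic, x$fraction_central))
  invisible(x)
}

#' Read or write a pool TSV
#'
#' Column layout: `barcode scaffold pos strand nReads geneId central
#' multimapped`; missing gene assignments are written as `NA`. Writing then
#' reading reproduces the pool exactly.
#'
#' @param pool Pool table.
#' @param path File path.
#' @return `read_pool_tsv` returns the pool data.frame.
#' @export
write_pool_tsv <- function(pool, path) {
  out <- data.frame(barcode = pool$barcode, scaffold = pool$scaffold,
                    pos = pool$pos, strand = pool$strand,
                    nReads = pool$n_reads, geneId = pool$gene_id,
                    central = pool$central, multimapped = pool$multimapped)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    barcode = "character", scaffold = "character", pos = "integer",
    strand = "character", nReads = "integer", geneId = "character",
    central = "logical", multimapped = "logical"))
  data.frame(barcode = df$barcode, scaffold = df$scaffold, pos = df$pos,
             strand = df$strand, n_reads = df$nReads, gene_id = df$geneId,
             central = df$central, multimapped = df$multimapped,
             stringsAsFactors = FALSE)
}
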