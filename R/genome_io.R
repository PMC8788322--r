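# Genome and annotation I/O. All coordinates are 1-based inclusive (GFF3
# convention); any half-open arithmetic stays inside individual functions.

#' Read a genome FASTA file
#'
#' Reads a (multi-record) FASTA file into a genome table with one row per
#' scaffold. Sequences are uppercased and validated against the alphabet
#' {A, C, G, T, N}.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A data.frame with columns `scaffold_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seq_chr <- toupper(as.character(seqs))
  bad <- gsub("[ACGTN]", "", seq_chr)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1L]
    stop("invalid character '", substr(bad[i], 1L, 1L),
         "' in sequence of scaffold '", ids[i], "'")
  }
  data.frame(scaffold_id = unname(ids), sequence = unname(seq_chr),
             length = unname(nchar(seq_chr)), stringsAsFactors = FALSE)
}

#' Write a genome table to FASTA
#'
#' @param genome Genome table as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genome))) {
    writeLines(paste0(">", genome$scaffold_id[i]), con)
    s <- genome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Parse a GFF3 attribute column into a named character vector.
parse_gff_attributes <- function(attr) {
  if (is.na(attr) || attr == "." || attr == "") return(character())
  parts <- strsplit(attr, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) >= 2L) x[2L] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Read gene annotations from a GFF3 file
#'
#' Retains only rows of the requested feature type. The primary identifier
#' is taken from `locus_tag` (falling back to `ID`), and any
#' `old_locus_tag`/`Name` values are kept as comma-separated aliases.
#' Rows are sorted by (scaffold, start).
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to retain (column 3), default `"gene"`.
#' @param genome Optional genome table; if given, scaffold ids and
#'   coordinates are validated against it.
#' @return A data.frame with columns `gene_id`, `aliases`, `scaffold_id`,
#'   `start`, `end`, `strand`, `product`, `length`.
#' @export
read_gff <- function(path, feature_type = "gene", genome = NULL) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  rows <- which(keep)
  out <- vector("list", length(rows))
  n <- 0L
  for (ln in rows) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      stop("malformed GFF row (", length(f), " columns, expected 9) at line ",
           ln, " of ", path)
    }
    if (f[3L] != feature_type) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop("non-integer coordinates at line ", ln, " of ", path)
    }
    if (end < start) stop("end < start at line ", ln, " of ", path)
    at <- parse_gff_attributes(f[9L])
    gene_id <- if ("locus_tag" %in% names(at)) at[["locus_tag"]]
               else if ("ID" %in% names(at)) at[["ID"]]
               else stop("no locus_tag or ID attribute at line ", ln)
    aliases <- unname(at[names(at) %in% c("old_locus_tag", "Name")])
    aliases <- aliases[aliases != gene_id]
    n <- n + 1L
    out[[n]] <- data.frame(
      gene_id = gene_id,
      aliases = paste(aliases, collapse = ","),
      scaffold_id = f[1L], start = start, end = end, strand = f[7L],
      product = if ("product" %in% names(at)) at[["product"]] else "",
      stringsAsFactors = FALSE)
  }
  if (n == 0L) stop("no '", feature_type, "' features found in ", path)
  genes <- do.call(rbind, out[seq_len(n)])
  genes$length <- genes$end - genes$start + 1L
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!is.null(genome)) {
    miss <- setdiff(genes$scaffold_id, genome$scaffold_id)
    if (length(miss)) stop("scaffold(s) not in genome: ", paste(miss, collapse = ", "))
    len <- genome$length[match(genes$scaffold_id, genome$scaffold_id)]
    if (any(genes$end > len)) {
      stop("gene(s) extend beyond scaffold end: ",
           paste(genes$gene_id[genes$end > len], collapse = ", "))
    }
  }
  genes <- genes[order(genes$scaffold_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene annotations to GFF3
#'
#' Inverse of [read_gff()]: the written file round-trips through
#' [read_gff()] with all fields preserved.
#'
#' @param genes Gene table as returned by [read_gff()].
#' @param path Output path.
#' @param feature_type Feature type for column 3.
#' @export
write_gff <- function(genes, path, feature_type = "gene") {
  attrs <- vapply(seq_len(nrow(genes)), function(i) {
    a <- paste0("ID=", genes$gene_id[i], ";locus_tag=", genes$gene_id[i])
    if (nzchar(genes$aliases[i])) a <- paste0(a, ";old_locus_tag=", genes$aliases[i])
    if (nzchar(genes$product[i])) a <- paste0(a, ";product=", genes$product[i])
    a
  }, "")
  lines <- paste(genes$scaffold_id, "magscreen", feature_type,
                 genes$start, genes$end, ".", genes$strand, ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Central region of a gene
#'
#' The interval of a gene in which a transposon insertion is considered
#' disruptive. With the default fractions (0.1, 0.9) the outermost 10% at
#' each end is excluded, following RB-TnSeq convention: terminal insertions
#' often leave a functional product.
#'
#' The interval is `[start + floor(lo_frac * length),
#' start + ceiling(hi_frac * length) - 1]`, clamped to `[start, end]`;
#' it is always nonempty and widening the fractions never shrinks it.
#'
#' @param start,end 1-based inclusive gene coordinates (vectorized).
#' @param lo_frac,hi_frac Fractions of the gene length delimiting the
#'   region, `0 <= lo_frac < hi_frac <= 1`.
#' @return A data.frame with columns `lo`, `hi` (1-based inclusive).
#' @export
central_region <- function(start, end, lo_frac = 0.1, hi_frac = 0.9) {
  if (length(lo_frac) != 1L || length(hi_frac) != 1L ||
      is.na(lo_frac) || is.na(hi_frac) ||
      lo_frac < 0 || hi_frac > 1 || lo_frac >= hi_frac) {
    stop("invalid fractions: need 0 <= lo_frac < hi_frac <= 1")
  }
  if (any(end < start)) stop("end < start")
  len <- end - start + 1L
  lo <- start + floor(lo_frac * len)
  hi <- start + ceiling(hi_frac * len) - 1L
  lo <- pmax(pmin(lo, end), start)
  hi <- pmin(pmax(hi, lo), end)
  data.frame(lo = as.integer(lo), hi = as.integer(hi))
}
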