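# BarSeq demultiplexing and barcode counting. Reads are
# `sample index | constant flank | barcode (20 nt)`; counts are tabulated
# against the known pool only, with off-pool barcodes tallied per sample.

#' BarSeq read model
#'
#' @param flank5 Constant sequence between the sample index and the
#'   barcode; default matches the bundled simulator.
#' @param barcode_len Barcode length in nt.
#' @return A list of class `barseq_model`.
#' @export
barseq_model <- function(flank5 = "GTCGACGGTATCGATAAG", barcode_len = 20L) {
  stopifnot(nchar(flank5) > 0, barcode_len >= 1)
  structure(list(flank5 = toupper(flank5),
                 barcode_len = as.integer(barcode_len)),
            class = "barseq_model")
}

#' Read and validate a sample sheet
#'
#' Columns: `sampleId`, `condition`, `fraction`, `replicate`, `index`.
#' Fractions must be one of `t0`, `precolumn`, `magnetic`, `nonmagnetic`.
#' Sample ids and index sequences must be unique, index sequences must all
#' have the same length, and every (condition, replicate) with a magnetic
#' or nonmagnetic sample must also have a precolumn sample (required for
#' MCS normalization).
#'
#' @param path Sample sheet TSV path.
#' @return Validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, colClasses = c(
    sampleId = "character", condition = "character", fraction = "character",
    replicate = "integer", index = "character"))
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sampleId", "condition", "fraction", "replicate", "index")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sampleId)) stop("duplicate sampleId in sample sheet")
  if (anyDuplicated(sheet$index)) stop("duplicate index sequence in sample sheet")
  bad <- setdiff(unique(sheet$fraction), c("t0", "precolumn", "magnetic", "nonmagnetic"))
  if (length(bad)) stop("unknown fraction(s): ", paste(bad, collapse = ", "))
  if (length(unique(nchar(sheet$index))) != 1L) {
    stop("all index sequences must have the same length")
  }
  if (any(sheet$replicate < 1L)) stop("replicate must be >= 1")
  key <- paste(sheet$condition, sheet$replicate)
  col_key <- unique(key[sheet$fraction %in% c("magnetic", "nonmagnetic")])
  pre_key <- unique(key[sheet$fraction == "precolumn"])
  missing_pre <- setdiff(col_key, pre_key)
  if (length(missing_pre)) {
    stop("no precolumn sample for condition/replicate: ",
         paste(missing_pre, collapse = "; "))
  }
  sheet
}

#' Write a sample sheet TSV
#' @param sheet Sample sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse one BarSeq read
#'
#' Matches the read's index prefix exactly against the sample sheet, checks
#' the constant flank immediately after it, and extracts the barcode.
#'
#' @param read A single read sequence.
#' @param model A [barseq_model()].
#' @param sheet A validated sample sheet.
#' @return A list with `status = "ok"`, `sample_id`, `barcode`, or
#'   `status = "reject"` with `reason` in `index_unknown`, `flank_missing`,
#'   `barcode_N`.
#' @export
parse_barseq_read <- function(read, model = barseq_model(), sheet) {
  p <- parse_barseq_reads(read, model, sheet)
  if (is.na(p$sample_id)) list(status = "reject", reason = p$reason)
  else list(status = "ok", sample_id = p$sample_id, barcode = p$barcode)
}

# Vectorized BarSeq parser.
parse_barseq_reads <- function(reads, model, sheet) {
  reads <- toupper(reads)
  ilen <- nchar(sheet$index[1L])
  nf <- nchar(model$flank5)
  blen <- model$barcode_len
  idx <- substr(reads, 1L, ilen)
  row <- match(idx, toupper(sheet$index))
  flank <- substr(reads, ilen + 1L, ilen + nf)
  barcode <- substr(reads, ilen + nf + 1L, ilen + nf + blen)
  reason <- rep(NA_character_, length(reads))
  reason[is.na(row)] <- "index_unknown"
  badf <- is.na(reason) & flank != model$flank5
  reason[badf] <- "flank_missing"
  badb <- is.na(reason) & (nchar(barcode) < blen | grepl("N", barcode, fixed = TRUE))
  reason[badb] <- "barcode_N"
  ok <- is.na(reason)
  data.frame(sample_id = ifelse(ok, sheet$sampleId[row], NA_character_),
             barcode = ifelse(ok, barcode, NA_character_),
             reason = reason, stringsAsFactors = FALSE)
}

#' Count pool barcodes per sample from BarSeq reads
#'
#' Only barcodes present in the pool become rows; off-pool barcodes
#' increment a per-sample unknown tally. Every pool barcode is retained as
#' a row even at zero counts so downstream pseudocounts are well defined.
#' Matching is exact (no mismatch rescue).
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param model A [barseq_model()].
#' @param sheet Validated sample sheet.
#' @param pool Pool table from [build_pool()].
#' @return A `count_matrix` object: list with `counts` (integer matrix,
#'   pool barcodes x samples), `unknown` (named integer vector per sample),
#'   `rejections` (tally by reason), and `sheet`.
#' @export
count_barcodes <- function(reads, model = barseq_model(), sheet, pool) {
  validate_sample_sheet(sheet)
  if (length(reads) == 1L && !grepl("^[ACGTN]+$", reads) && file.exists(reads)) {
    reads <- read_fastq_seqs(reads)
  }
  p <- parse_barseq_reads(reads, model, sheet)
  ok <- !is.na(p$sample_id)
  counts <- matrix(0L, nrow = nrow(pool), ncol = nrow(sheet),
                   dimnames = list(pool$barcode, sheet$sampleId))
  unknown <- stats::setNames(integer(nrow(sheet)), sheet$sampleId)
  if (any(ok)) {
    bi <- match(p$barcode[ok], pool$barcode)
    si <- match(p$sample_id[ok], sheet$sampleId)
    inpool <- !is.na(bi)
    if (any(inpool)) {
      tab <- table(bi[inpool], si[inpool])
      counts[cbind(as.integer(rownames(tab))[row(tab)],
                   as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    }
    if (any(!inpool)) {
      ut <- table(si[!inpool])
      unknown[as.integer(names(ut))] <- as.integer(ut)
    }
  }
  empty <- colSums(counts) + unknown == 0L
  if (any(empty)) {
    warning("sample(s) received zero reads: ",
            paste(sheet$sampleId[empty], collapse = ", "))
  }
  new_count_matrix(counts, unknown, sheet,
                   rejections = as.list(table(p$reason[!ok])))
}

new_count_matrix <- function(counts, unknown, sheet, rejections = list()) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, unknown = unknown, sheet = sheet,
                 rejections = rejections),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("BarSeq count matrix: %d barcodes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  column totals: ", paste(colSums(x$counts), collapse = " "), "\n")
  cat("  unknown-barcode reads: ", paste(x$unknown, collapse = " "), "\n")
  invisible(x)
}

#' Read or write a barcode count TSV
#'
#' First column `barcode`, one column per sample in sheet order. A leading
#' `#unknown` comment line preserves the per-sample off-pool tallies.
#' The round trip is lossless for counts and unknown tallies (the sample
#' sheet itself is stored separately).
#'
#' @param x A `count_matrix`.
#' @param path File path.
#' @return `read_counts_tsv` returns a `count_matrix` (with `sheet = NULL`
#'   unless supplied).
#' @export
write_counts_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#unknown", x$unknown), collapse = "\t"), con)
  df <- data.frame(barcode = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param sheet Optional sample sheet to attach to the returned object.
#' @export
read_counts_tsv <- function(path, sheet = NULL) {
  first <- readLines(path, n = 1L)
  unknown_line <- startsWith(first, "#unknown")
  df <- utils::read.delim(path, skip = if (unknown_line) 1L else 0L,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("count TSV has no barcode rows: ", path)
  mat_chr <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(mat_num <- apply(mat_chr, 2L, as.numeric))
  if (!is.matrix(mat_num)) mat_num <- matrix(mat_num, nrow = nrow(mat_chr),
                                             dimnames = dimnames(mat_chr))
  bad <- which(is.na(mat_num) | mat_num < 0 | mat_num != floor(mat_num),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count at barcode '", df$barcode[bad[1L, 1L]], "', sample '",
         colnames(mat_chr)[bad[1L, 2L]], "': ", mat_chr[bad[1L, , drop = FALSE]])
  }
  counts <- matrix(as.integer(mat_num), nrow = nrow(mat_num),
                   dimnames = list(df$barcode, colnames(mat_chr)))
  unknown <- stats::setNames(integer(ncol(counts)), colnames(counts))
  if (unknown_line) {
    vals <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
    unknown <- stats::setNames(as.integer(vals), colnames(counts))
  }
  new_count_matrix(counts, unknown, sheet)
}
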