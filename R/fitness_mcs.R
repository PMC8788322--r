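# Gene-level magnetic column scores (MCS). Strain scores are log2 abundance
# ratios of a sample versus its time-zero reference (total-count normalized,
# pseudocount 1); gene scores are inverse-variance weighted means over
# central, uniquely mapped strains; the normalized MCS subtracts the
# precolumn gene score from the magnetic and nonmagnetic gene scores so
# growth defects cancel.

#' Scoring configuration
#'
#' @param pseudo Pseudocount added to strain counts (default 1).
#' @param t0_min_reads Minimum time-zero reads for a strain to be scored
#'   (default 3); low-count t0 strains give unstable ratios.
#' @param min_strains_per_gene Minimum eligible strains for a gene score
#'   (default 1); genes below it are omitted, not scored 0.
#' @param median_center Subtract the per-sample median gene raw score
#'   before MCS normalization (default FALSE; a simplification of the
#'   smoothing normalization used for real growth-fitness data).
#' @param hit_threshold Absolute replicate-mean MCS needed to call a hit
#'   (default 1).
#' @param require_consistent_sign Drop hits whose replicates disagree in
#'   sign (default TRUE).
#' @return A list of class `score_config`.
#' @export
score_config <- function(pseudo = 1, t0_min_reads = 3L,
                         min_strains_per_gene = 1L, median_center = FALSE,
                         hit_threshold = 1, require_consistent_sign = TRUE) {
  stopifnot(pseudo > 0, t0_min_reads >= 0, min_strains_per_gene >= 1)
  structure(list(pseudo = pseudo, t0_min_reads = as.integer(t0_min_reads),
                 min_strains_per_gene = as.integer(min_strains_per_gene),
                 median_center = isTRUE(median_center),
                 hit_threshold = hit_threshold,
                 require_consistent_sign = isTRUE(require_consistent_sign)),
            class = "score_config")
}

#' Strain score: log2 normalized abundance ratio
#'
#' `log2( ((n_cond + pseudo) / total_cond) / ((n_t0 + pseudo) / total_t0) )`.
#' With equal totals this reduces to `log2((n_cond+pseudo)/(n_t0+pseudo))`.
#' Vectorized over counts.
#'
#' @param n_cond,n_t0 Strain read counts in the condition and time-zero
#'   samples (nonnegative).
#' @param total_cond,total_t0 Per-sample total read counts (> 0).
#' @param pseudo Pseudocount (default 1).
#' @return Numeric score(s) in log2 units.
#' @export
strain_score <- function(n_cond, n_t0, total_cond, total_t0, pseudo = 1) {
  if (any(n_cond < 0) || any(n_t0 < 0)) stop("negative counts")
  if (any(total_cond <= 0) || any(total_t0 <= 0)) stop("totals must be > 0")
  log2(((n_cond + pseudo) / total_cond) / ((n_t0 + pseudo) / total_t0))
}

#' Inverse-variance strain weight
#'
#' Poisson-motivated variance of a strain's log2 ratio:
#' `V = (1/(1+n_cond) + 1/(1+n_t0)) / ln(2)^2`; the weight is `1/V`.
#' Balanced counts give equal weights, so the gene score reduces to a plain
#' mean on balanced data.
#'
#' @inheritParams strain_score
#' @return Numeric weight(s) > 0.
#' @export
strain_weight <- function(n_cond, n_t0) {
  log(2)^2 / (1 / (1 + n_cond) + 1 / (1 + n_t0))
}

#' Weighted gene score from strain scores
#'
#' `sum(w * f) / sum(w)`; equal (or absent) weights give the arithmetic
#' mean, a single strain gives its own score.
#'
#' @param scores Numeric strain scores.
#' @param weights Optional positive weights (default equal).
#' @return The weighted mean score.
#' @export
gene_score <- function(scores, weights = NULL) {
  if (length(scores) == 0L) stop("no eligible strains")
  if (is.null(weights)) weights <- rep(1, length(scores))
  if (length(weights) != length(scores)) stop("scores/weights length mismatch")
  if (any(!is.finite(weights)) || any(weights <= 0)) stop("weights must be finite and > 0")
  sum(weights * scores) / sum(weights)
}

#' Gene raw scores, normalized MCS, and replicate means
#'
#' For each non-t0 sample, each eligible strain (central, uniquely mapped,
#' with at least `t0_min_reads` reads in the matching time-zero sample) is
#' scored against the t0 sample of the same condition and replicate; gene
#' raw scores are inverse-variance weighted means. The normalized MCS per
#' (gene, condition, replicate, fraction in magnetic/nonmagnetic) is the
#' raw score minus the precolumn raw score; replicate means are arithmetic
#' means over available replicates.
#'
#' @param cm A `count_matrix` from [count_barcodes()] or [read_counts_tsv()].
#' @param pool Pool table from [build_pool()].
#' @param sheet Sample sheet (defaults to the one stored in `cm`).
#' @param config A [score_config()].
#' @return A list of class `gene_scores`: `raw` (gene x sample raw scores),
#'   `norm` (per-replicate normalized MCS), `means` (replicate-mean MCS with
#'   `n_rep` and `consistent_sign`), `config`.
#' @export
score_genes <- function(cm, pool, sheet = cm$sheet, config = score_config()) {
  if (is.null(sheet)) stop("no sample sheet available")
  validate_sample_sheet(sheet)
  counts <- cm$counts
  el_pool <- pool[pool$central & !pool$multimapped & !is.na(pool$gene_id), , drop = FALSE]
  if (nrow(el_pool) == 0L) stop("no eligible strains in pool")
  bi <- match(el_pool$barcode, rownames(counts))
  if (anyNA(bi)) stop("pool barcodes missing from count matrix")
  totals <- colSums(counts)
  if (any(totals[sheet$sampleId[sheet$fraction != "t0"]] == 0)) {
    warning("sample(s) with zero total counts are skipped")
  }

  t0_of <- function(cond, rep) {
    sheet$sampleId[sheet$fraction == "t0" & sheet$condition == cond &
                   sheet$replicate == rep]
  }
  raw <- list(); nr <- 0L
  for (i in which(sheet$fraction != "t0")) {
    sid <- sheet$sampleId[i]
    t0 <- t0_of(sheet$condition[i], sheet$replicate[i])
    if (length(t0) != 1L) {
      stop("need exactly one t0 sample for condition '", sheet$condition[i],
           "' replicate ", sheet$replicate[i], " (found ", length(t0), ")")
    }
    if (totals[sid] == 0 || totals[t0] == 0) next
    n_cond <- counts[bi, sid]
    n_t0 <- counts[bi, t0]
    elig <- n_t0 >= config$t0_min_reads
    if (!any(elig)) next
    sc <- strain_score(n_cond[elig], n_t0[elig], totals[sid], totals[t0],
                       config$pseudo)
    w <- strain_weight(n_cond[elig], n_t0[elig])
    g <- el_pool$gene_id[elig]
    gs <- vapply(split(seq_along(sc), g), function(ii) {
      if (length(ii) < config$min_strains_per_gene) return(NA_real_)
      gene_score(sc[ii], w[ii])
    }, 0)
    keep <- !is.na(gs)
    if (!any(keep)) next
    nstr <- as.integer(table(g))[keep]
    nr <- nr + 1L
    raw[[nr]] <- data.frame(gene_id = names(gs)[keep], sample_id = sid,
                            condition = sheet$condition[i],
                            fraction = sheet$fraction[i],
                            replicate = sheet$replicate[i],
                            score = unname(gs[keep]), n_strains = nstr,
                            stringsAsFactors = FALSE)
  }
  if (nr == 0L) stop("no samples could be scored")
  raw <- do.call(rbind, raw)
  if (config$median_center) {
    med <- tapply(raw$score, raw$sample_id, stats::median)
    raw$score <- raw$score - med[raw$sample_id]
  }
  norm <- normalize_mcs(raw)
  means <- replicate_mean(norm)
  structure(list(raw = raw, norm = norm, means = means, config = config),
            class = "gene_scores")
}

#' Normalize gene scores against the precolumn fraction
#'
#' `MCS(gene, fraction, replicate) = raw(fraction) - raw(precolumn)` for
#' fraction in magnetic/nonmagnetic, matched within (condition, replicate).
#' Genes scored in only one of the two samples are dropped (tallied in the
#' `coverage` attribute). Pure growth effects shift the condition and
#' precolumn scores equally and therefore cancel.
#'
#' @param raw Data.frame of gene raw scores as produced by [score_genes()]
#'   (columns `gene_id`, `condition`, `fraction`, `replicate`, `score`).
#' @return Data.frame with columns `gene_id`, `condition`, `fraction`,
#'   `replicate`, `mcs`, `n_strains`.
#' @export
normalize_mcs <- function(raw) {
  pre <- raw[raw$fraction == "precolumn", , drop = FALSE]
  col <- raw[raw$fraction %in% c("magnetic", "nonmagnetic"), , drop = FALSE]
  if (nrow(col) == 0L) stop("no magnetic/nonmagnetic samples to normalize")
  need <- unique(col[, c("condition", "replicate")])
  have <- unique(pre[, c("condition", "replicate")])
  miss <- setdiff(paste(need$condition, need$replicate),
                  paste(have$condition, have$replicate))
  if (length(miss)) {
    stop("missing precolumn sample for condition/replicate: ",
         paste(miss, collapse = "; "))
  }
  key_pre <- paste(pre$gene_id, pre$condition, pre$replicate, sep = "\r")
  key_col <- paste(col$gene_id, col$condition, col$replicate, sep = "\r")
  m <- match(key_col, key_pre)
  found <- !is.na(m)
  out <- data.frame(gene_id = col$gene_id[found],
                    condition = col$condition[found],
                    fraction = col$fraction[found],
                    replicate = col$replicate[found],
                    mcs = col$score[found] - pre$score[m[found]],
                    n_strains = col$n_strains[found],
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- c(n_scored = sum(found), n_dropped = sum(!found))
  out
}

#' Replicate-mean MCS per gene
#'
#' Arithmetic mean of the normalized MCS over available replicates, with
#' the replicate count and a sign-consistency flag (all replicates sharing
#' the sign of the mean).
#'
#' @param norm Normalized MCS data.frame from [normalize_mcs()].
#' @param condition,fraction Optional filters.
#' @return Data.frame with columns `gene_id`, `condition`, `fraction`,
#'   `mean_mcs`, `n_rep`, `consistent_sign`.
#' @export
replicate_mean <- function(norm, condition = NULL, fraction = NULL) {
  if (!is.null(condition)) norm <- norm[norm$condition %in% condition, , drop = FALSE]
  if (!is.null(fraction)) norm <- norm[norm$fraction %in% fraction, , drop = FALSE]
  if (nrow(norm) == 0L) stop("no normalized scores after filtering")
  key <- paste(norm$gene_id, norm$condition, norm$fraction, sep = "\r")
  agg <- lapply(split(seq_len(nrow(norm)), key), function(ii) {
    m <- mean(norm$mcs[ii])
    data.frame(gene_id = norm$gene_id[ii[1L]],
               condition = norm$condition[ii[1L]],
               fraction = norm$fraction[ii[1L]],
               mean_mcs = m, n_rep = length(ii),
               consistent_sign = all(sign(norm$mcs[ii]) == sign(m)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$condition, out$fraction, out$gene_id), , drop = FALSE]
}

#' Call hit genes from replicate-mean MCS
#'
#' Depleted hits have `mean_mcs <= -threshold` (candidate biomineralization
#' defects when the fraction is magnetic); enriched hits have
#' `mean_mcs >= threshold`. The threshold is a package convention, not a
#' published cutoff; sign consistency across replicates is required by
#' default.
#'
#' @param scores A `gene_scores` object from [score_genes()], or a
#'   replicate-mean data.frame from [replicate_mean()].
#' @param threshold Absolute mean MCS cutoff (default 1).
#' @param require_consistent_sign Drop sign-inconsistent candidates
#'   (default TRUE).
#' @return Data.frame with columns `gene_id`, `condition`, `fraction`,
#'   `mean_mcs`, `direction`, `consistent_sign`.
#' @export
call_hits <- function(scores, threshold = 1, require_consistent_sign = TRUE) {
  means <- if (inherits(scores, "gene_scores")) scores$means else scores
  cand <- means[abs(means$mean_mcs) >= threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(gene_id = character(), condition = character(),
                      fraction = character(), mean_mcs = numeric(),
                      direction = character(), consistent_sign = logical(),
                      stringsAsFactors = FALSE))
  }
  cand$direction <- ifelse(cand$mean_mcs <= -threshold, "depleted", "enriched")
  if (require_consistent_sign) cand <- cand[cand$consistent_sign, , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("gene_id", "condition", "fraction", "mean_mcs", "direction",
           "consistent_sign")]
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("Gene scores: %d raw gene x sample scores, %d normalized MCS rows\n",
              nrow(x$raw), nrow(x$norm)))
  cat(sprintf("  conditions: %s\n", paste(unique(x$raw$condition), collapse = ", ")))
  cat(sprintf("  fractions scored: %s\n", paste(unique(x$raw$fraction), collapse = ", ")))
  invisible(x)
}

#' Write per-condition score tables
#'
#' One TSV per condition x fraction with columns
#' `geneId rep1 ... repK meanMCS nStrains`.
#'
#' @param scores A `gene_scores` object.
#' @param dir Output directory (created if needed).
#' @return Paths of files written, invisibly.
#' @export
write_score_tables <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  norm <- scores$norm
  for (cond in unique(norm$condition)) {
    for (frac in unique(norm$fraction[norm$condition == cond])) {
      sub <- norm[norm$condition == cond & norm$fraction == frac, , drop = FALSE]
      reps <- sort(unique(sub$replicate))
      wide <- stats::reshape(
        sub[, c("gene_id", "replicate", "mcs")], idvar = "gene_id",
        timevar = "replicate", direction = "wide")
      names(wide) <- c("geneId", paste0("rep", reps))
      mm <- scores$means[scores$means$condition == cond &
                         scores$means$fraction == frac, , drop = FALSE]
      wide$meanMCS <- mm$mean_mcs[match(wide$geneId, mm$gene_id)]
      ns <- tapply(sub$n_strains, sub$gene_id, max)
      wide$nStrains <- as.integer(ns[wide$geneId])
      p <- file.path(dir, paste0("scores_", gsub("[^A-Za-z0-9_.-]", "_", cond),
                                 "_", frac, ".tsv"))
      utils::write.table(wide, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
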