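# Essential-gene calling from insertion density. A gene is called essential
# when it is long enough that zero central insertions would be improbable
# under a Poisson model at the library's median insertion density, and it
# nevertheless has none.

#' Configuration for essential-gene calling
#'
#' @param alpha Poisson tail probability for the minimum-length threshold
#'   (default 0.02).
#' @param min_gene_len Genes shorter than this (nt) are excluded from the
#'   analysis entirely (default 100).
#' @param duplicate_policy How duplicate (repeat-like) genes are detected:
#'   `"multimap_fraction"` flags genes whose barcodes are mostly
#'   multimapped; `"user_list"` uses `duplicate_genes` only.
#' @param multimap_fraction_cutoff Fraction of a gene's barcodes that must
#'   be multimapped to flag it under `"multimap_fraction"` (default 0.5).
#' @param duplicate_genes Character vector of gene ids to exclude as
#'   duplicates regardless of policy.
#' @param lo_frac,hi_frac Central-region fractions (see [central_region()]).
#' @param low_density_frac Advisory flag: genes with density below this
#'   multiple of the median are reported as low-density (default 0.2).
#' @return A list of class `essentiality_config`.
#' @export
essentiality_config <- function(alpha = 0.02, min_gene_len = 100L,
                                duplicate_policy = c("multimap_fraction", "user_list"),
                                multimap_fraction_cutoff = 0.5,
                                duplicate_genes = character(),
                                lo_frac = 0.1, hi_frac = 0.9,
                                low_density_frac = 0.2) {
  stopifnot(alpha > 0, alpha < 1, min_gene_len >= 1)
  structure(list(alpha = alpha, min_gene_len = as.integer(min_gene_len),
                 duplicate_policy = match.arg(duplicate_policy),
                 multimap_fraction_cutoff = multimap_fraction_cutoff,
                 duplicate_genes = duplicate_genes,
                 lo_frac = lo_frac, hi_frac = hi_frac,
                 low_density_frac = low_density_frac),
            class = "essentiality_config")
}

#' Poisson minimum gene length for essentiality calling
#'
#' The shortest gene length L (nt) at which observing zero insertions is
#' unlikely by chance: the smallest integer L with
#' `exp(-median_density * L) < alpha`, i.e.
#' `floor(-log(alpha) / median_density) + 1`.
#'
#' @param median_density Median insertion density over analyzed genes
#'   (insertions per nt), must be > 0.
#' @param alpha Tail probability (default 0.02).
#' @return Integer minimum length in nt.
#' @export
poisson_min_length <- function(median_density, alpha = 0.02) {
  if (!is.finite(median_density) || median_density <= 0) {
    stop("median_density must be > 0")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  as.integer(floor(-log(alpha) / median_density)) + 1L
}

#' Per-gene insertion densities with exclusion flags
#'
#' Counts central, uniquely mapped strains per gene and divides by the
#' central-region length. Genes shorter than `min_gene_len` are flagged
#' `excluded_short`; genes on the duplicate list, or (under the
#' multimap-fraction policy) genes whose assigned barcodes are mostly
#' multimapped, are flagged `excluded_duplicate`. The median density is
#' computed over non-excluded genes.
#'
#' @param pool Pool table from [build_pool()].
#' @param genes Gene table from [read_gff()].
#' @param config An [essentiality_config()].
#' @return A data.frame (one row per annotated gene) with columns
#'   `gene_id`, `length`, `central_length`, `n_central_strains`, `density`,
#'   `excluded`; attribute `median_density`.
#' @export
compute_densities <- function(pool, genes, config = essentiality_config()) {
  cr <- central_region(genes$start, genes$end, config$lo_frac, config$hi_frac)
  central_len <- cr$hi - cr$lo + 1L
  cen <- pool[pool$central & !pool$multimapped & !is.na(pool$gene_id), , drop = FALSE]
  n_central <- as.integer(table(factor(cen$gene_id, levels = genes$gene_id)))
  excluded <- rep(NA_character_, nrow(genes))
  excluded[genes$length < config$min_gene_len] <- "excluded_short"
  dup <- genes$gene_id %in% config$duplicate_genes
  if (config$duplicate_policy == "multimap_fraction") {
    assigned <- pool[!is.na(pool$gene_id), , drop = FALSE]
    mmf <- tapply(assigned$multimapped, factor(assigned$gene_id, levels = genes$gene_id), mean)
    mmf[is.na(mmf)] <- 0
    dup <- dup | (mmf >= config$multimap_fraction_cutoff & as.integer(table(
      factor(assigned$gene_id, levels = genes$gene_id))) > 0L)
  }
  excluded[is.na(excluded) & dup] <- "excluded_duplicate"
  out <- data.frame(gene_id = genes$gene_id, length = genes$length,
                    central_length = central_len,
                    n_central_strains = n_central,
                    density = n_central / central_len,
                    excluded = excluded, stringsAsFactors = FALSE)
  keep <- is.na(excluded)
  if (!any(keep)) stop("all genes excluded from essentiality analysis")
  attr(out, "median_density") <- stats::median(out$density[keep])
  out
}

#' Call essential genes
#'
#' Classifies every annotated gene into one of: `essential` (call-eligible,
#' zero central strains), `nonessential` (call-eligible with insertions, or
#' any non-excluded gene with insertions), `not_called_below_threshold`
#' (shorter than the Poisson minimum length `L_min`), `excluded_short`,
#' `excluded_duplicate`. The classes partition the annotated gene set.
#'
#' @inheritParams compute_densities
#' @return A list of class `essentiality_calls`: `calls` (per-gene
#'   data.frame with `gene_id`, `class`, `n_central_strains`, `central_len`,
#'   `density`, `low_density`) and `summary` (list with `L_min`, `alpha`,
#'   `median_density`, `class_counts`).
#' @export
call_essentials <- function(pool, genes, config = essentiality_config()) {
  dens <- compute_densities(pool, genes, config)
  d_med <- attr(dens, "median_density")
  if (d_med <= 0) stop("median insertion density is zero; library too sparse")
  L_min <- poisson_min_length(d_med, config$alpha)
  cls <- rep("nonessential", nrow(dens))
  cls[!is.na(dens$excluded)] <- dens$excluded[!is.na(dens$excluded)]
  below <- is.na(dens$excluded) & dens$length < L_min
  cls[below] <- "not_called_below_threshold"
  ess <- is.na(dens$excluded) & dens$length >= L_min & dens$n_central_strains == 0L
  cls[ess] <- "essential"
  calls <- data.frame(gene_id = dens$gene_id, class = cls,
                      n_central_strains = dens$n_central_strains,
                      central_len = dens$central_length,
                      density = dens$density,
                      low_density = is.na(dens$excluded) &
                        dens$density < config$low_density_frac * d_med,
                      stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("essential", "nonessential",
                                         "not_called_below_threshold",
                                         "excluded_short", "excluded_duplicate")))
  structure(list(calls = calls,
                 summary = list(L_min = L_min, alpha = config$alpha,
                                median_density = d_med,
                                class_counts = as.list(counts))),
            class = "essentiality_calls")
}

#' @export
print.essentiality_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Essentiality calls (alpha = %g, L_min = %d nt, median density = %.4g /nt)\n",
              s$alpha, s$L_min, s$median_density))
  for (nm in names(s$class_counts)) {
    cat(sprintf("  %-28s %d\n", nm, s$class_counts[[nm]]))
  }
  invisible(x)
}

#' Write essentiality calls to TSV (+ JSON summary)
#'
#' @param x An `essentiality_calls` object.
#' @param path Output TSV path; the summary goes to `paste0(path, ".json")`.
#' @export
write_essentials <- function(x, path) {
  out <- data.frame(geneId = x$calls$gene_id, class = x$calls$class,
                    nCentralStrains = x$calls$n_central_strains,
                    centralLen = x$calls$central_len,
                    density = x$calls$density)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
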