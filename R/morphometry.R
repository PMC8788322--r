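# Magnetosome morphometry: summary statistics for crystal-length samples
# and the normality-gated two-sample comparison (Shapiro-Wilk on each
# sample; Student's t when both pass, Mann-Whitney U otherwise).

#' Construct a magnetosome length sample
#'
#' @param lengths Numeric vector of magnetosome lengths in nm (> 0).
#' @param strain,condition Labels.
#' @return A list of class `length_sample`.
#' @export
length_sample <- function(lengths, strain = "", condition = "") {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("lengths must be finite and > 0")
  }
  if (length(lengths) < 200L) {
    warning("fewer than 200 measurements (n = ", length(lengths),
            "); per-strain TEM surveys conventionally measure >200")
  }
  structure(list(strain = strain, condition = condition, lengths = lengths,
                 n = length(lengths)), class = "length_sample")
}

as_lengths <- function(x) {
  if (inherits(x, "length_sample")) x$lengths else as.numeric(x)
}

#' Summarize a length sample
#'
#' @param sample A [length_sample()] or numeric vector (nm).
#' @return A list with `mean`, `sd` (sample sd, n-1 denominator), `n`.
#' @export
summarize_lengths <- function(sample) {
  x <- as_lengths(sample)
  if (length(x) < 2L) stop("need n >= 2")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Normality-gated two-sample comparison
#'
#' Both samples are first tested for normality with the Shapiro-Wilk test.
#' If both Shapiro p-values are >= `alpha`, a two-sided unpaired Student's
#' t test (equal variances; Welch behind `var_equal = FALSE`) compares the
#' means; otherwise a two-sided Mann-Whitney U test is used. The gate
#' depends only on the two Shapiro p-values, and swapping the samples
#' changes neither the test chosen nor the two-sided p-value.
#'
#' @param a,b [length_sample()]s or numeric vectors, each with n >= 3.
#' @param alpha Normality-gate level (default 0.05).
#' @param var_equal Use the equal-variance Student's t (default TRUE).
#' @return A list of class `morpho_test`: `test_used` (`"student_t"` or
#'   `"mann_whitney"`), `p_value`, `statistic`, `shapiro_p_a`,
#'   `shapiro_p_b`, `significant` (p < 0.05).
#' @export
normality_gated_compare <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  x <- as_lengths(a); y <- as_lengths(b)
  if (length(x) < 3L || length(y) < 3L) {
    stop("both samples need n >= 3 for the Shapiro-Wilk test")
  }
  sa <- stats::shapiro.test(x)$p.value
  sb <- stats::shapiro.test(y)$p.value
  if (sa >= alpha && sb >= alpha) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    res <- list(test_used = "student_t", p_value = tt$p.value,
                statistic = unname(tt$statistic))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    res <- list(test_used = "mann_whitney", p_value = wt$p.value,
                statistic = unname(wt$statistic))
  }
  structure(c(res, list(shapiro_p_a = sa, shapiro_p_b = sb,
                        significant = res$p_value < 0.05)),
            class = "morpho_test")
}

#' @export
print.morpho_test <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%ssignificant at 0.05)\n",
              if (x$test_used == "student_t") "Student's t" else "Mann-Whitney U",
              x$p_value, if (x$significant) "" else "not "))
  cat(sprintf("  Shapiro-Wilk p: %.4g, %.4g\n", x$shapiro_p_a, x$shapiro_p_b))
  invisible(x)
}

#' Read length measurements from long-format CSV
#'
#' Expected columns: `strain`, `condition`, `length_nm`.
#'
#' @param path CSV path.
#' @return A list of [length_sample()]s, one per strain x condition,
#'   named `strain.condition`.
#' @export
read_lengths_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "length_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, list(df$strain, df$condition), drop = TRUE),
                function(d) suppressWarnings(
                  length_sample(d$length_nm, d$strain[1L], d$condition[1L])))
  out
}

#' Pairwise normality-gated comparisons
#'
#' Applies [normality_gated_compare()] to every pair of samples, producing
#' a table of the kind used to report magnetosome-length significance.
#'
#' @param samples Named list of [length_sample()]s (as from
#'   [read_lengths_csv()]).
#' @param alpha Normality-gate level.
#' @return Data.frame with one row per pair: labels, means, test used,
#'   p-value, significance flag.
#' @export
morpho_compare_table <- function(samples, alpha = 0.05) {
  nm <- names(samples)
  if (length(samples) < 2L) stop("need at least two samples")
  rows <- list(); k <- 0L
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j <= i) next
      r <- normality_gated_compare(samples[[i]], samples[[j]], alpha)
      k <- k + 1L
      rows[[k]] <- data.frame(
        a = nm[i], b = nm[j],
        mean_a = mean(as_lengths(samples[[i]])),
        mean_b = mean(as_lengths(samples[[j]])),
        test_used = r$test_used, p_value = r$p_value,
        significant = r$significant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
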