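#' Normalize a raw read count to reads per million
#'
#' `normalized = count / total_clean_reads * 1e6`. A count of zero is
#' substituted by the pseudo-value 0.001 so that fold changes and log2 ratios
#' stay finite for library-specific miRNAs.
#'
#' @param x raw count(s), non-negative integers.
#' @param N total clean reads in the library (scalar or vector).
#' @param zero_value substitute used when `x == 0` (default 0.001).
#' @return numeric vector of normalized counts.
#' @examples
#' normalize_count(50, 1e7)   # 5
#' normalize_count(0, 1e7)    # 0.001
#' @export
normalize_count <- function(x, N, zero_value = 0.001) {
  assert_that(all(N > 0), "normalize_count(): N must be > 0")
  assert_that(all(x >= 0), "normalize_count(): counts must be >= 0")
  out <- x / N * 1e6
  out[x == 0] <- zero_value
  out
}

## log of the Audic-Claverie conditional probability p(k | x) for library-size
## ratio r = N2/N1:
##   p(k|x) = r^k * (x+k)! / (x! k! (1+r)^(x+k+1))
ac_log_pmf <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

## one-directional tails P(Y <= y | x) and P(Y >= y | x). Both tails are
## summed term-by-term from log-space pmf values; the upper tail is
## truncated once the horizon exceeds the distribution mean by 20 standard
## deviations and the running terms are below 1e-18, so no 1 - cumulative
## cancellation occurs.
ac_tails <- function(x, y, r) {
  lo <- sum(exp(ac_log_pmf(0:y, x, r)))
  mu <- (x + 1) * r
  horizon <- ceiling(mu + 20 * sqrt(max(mu * (1 + r), 1)) + 200)
  ks <- y:max(y, horizon)
  terms <- exp(ac_log_pmf(ks, x, r))
  hi <- sum(terms)
  while (terms[length(terms)] > 1e-18) {
    ks <- (max(ks) + 1):(max(ks) + 200)
    terms <- exp(ac_log_pmf(ks, x, r))
    hi <- hi + sum(terms)
  }
  c(lower = min(1, lo), upper = min(1, hi))
}

#' Audic-Claverie two-sided p-value for a two-library count comparison
#'
#' Exact test for whether a tag's counts `x` and `y`, observed in two
#' libraries with total clean-read depths `N1` and `N2`, are compatible with
#' equal underlying expression. Conditionally on `x`, the count in the second
#' library follows
#' \deqn{p(y|x) = \frac{(N_2/N_1)^y (x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' The two-sided p-value doubles the smaller tail, capped at 1, and is
#' symmetrized over the two conditioning directions (condition on `x` or on
#' `y`) so that `ac_pvalue(x, y, N1, N2) == ac_pvalue(y, x, N2, N1)` exactly.
#' Tail sums are accumulated from log-space terms so large counts do not
#' overflow.
#'
#' @param x,y raw counts (non-negative integers, vectorized).
#' @param N1,N2 total clean reads in the two libraries.
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' ac_pvalue(10, 0, 1e6, 1e6)   # 2^-10
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  assert_that(all(x >= 0) && all(y >= 0), "ac_pvalue(): counts must be >= 0")
  assert_that(all(N1 > 0) && all(N2 > 0), "ac_pvalue(): library sizes must be > 0")
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  vapply(seq_len(n), function(i) {
    t1 <- ac_tails(x[i], y[i], N2[i] / N1[i])
    t2 <- ac_tails(y[i], x[i], N1[i] / N2[i])
    p1 <- min(1, 2 * min(t1))
    p2 <- min(1, 2 * min(t2))
    min(p1, p2)
  }, numeric(1))
}

#' Classify differential expression of one miRNA between two libraries
#'
#' Builds the full differential-expression record for a miRNA from its raw
#' counts: normalized counts (reads per million, zero substituted by 0.001),
#' fold change, log2 ratio, Audic-Claverie p-value, fold-change class and
#' library-specificity call.
#'
#' The fold change is reported as `max(nx, ny) / min(nx, ny)` (always >= 1)
#' so that the three fold-change bands -- `high` (> 2), `mid` (1.2 to 2) and
#' `low` (< 1.2) -- partition all miRNAs; the direction is carried by the
#' sign of `log2_ratio = log2(nx / ny)`. A miRNA is flagged `de` when it is
#' significant (p < `alpha`) and in the `high` band; setting
#' `literal_low_band = TRUE` additionally flags significant `low`-band
#' miRNAs.
#'
#' @param mirna_id identifier(s).
#' @param x,y raw counts in the two libraries (conventionally MS and MF).
#' @param N1,N2 total clean reads per library.
#' @param alpha significance level (default 0.05).
#' @param high_band,low_band fold-change band edges (defaults 2 and 1.2).
#' @param literal_low_band also flag significant sub-1.2 fold changes as DE.
#' @return a `data.frame` of class `de_table` with one row per miRNA:
#'   `mirna_id, x, y, nx, ny, fold_change, log2_ratio, pvalue, de_class,
#'   significant, de, specificity`.
#' @export
de_classify <- function(mirna_id, x, y, N1, N2, alpha = 0.05,
                        high_band = 2, low_band = 1.2,
                        literal_low_band = FALSE) {
  nx <- normalize_count(x, N1)
  ny <- normalize_count(y, N2)
  fc <- pmax(nx, ny) / pmin(nx, ny)
  l2 <- log2(nx / ny)
  p <- ac_pvalue(x, y, N1, N2)
  de_class <- ifelse(fc > high_band, "high",
                     ifelse(fc >= low_band, "mid", "low"))
  significant <- p < alpha
  de <- significant & (de_class == "high" |
                         (literal_low_band & de_class == "low"))
  specificity <- ifelse(x > 0 & y == 0, "MS_only",
                        ifelse(x == 0 & y > 0, "MF_only", "common"))
  out <- data.frame(mirna_id = as.character(mirna_id), x = x, y = y,
                    nx = nx, ny = ny, fold_change = fc, log2_ratio = l2,
                    pvalue = p, de_class = de_class,
                    significant = significant, de = de,
                    specificity = specificity, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  if (all(c("de_class", "de") %in% names(x)))
    cat(sprintf("<de_table> %d miRNAs: %d high / %d mid / %d low band, %d DE (p < 0.05 & high)\n",
                nrow(x), sum(x$de_class == "high"), sum(x$de_class == "mid"),
                sum(x$de_class == "low"), sum(x$de)))
  NextMethod()
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR relative quantification of a target gene, normalized to a reference
#' gene and a calibrator sample:
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,calibrator - Ct_ref,calibrator))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator same, in the calibrator.
#' @return relative expression (1 means no change; ddCt of -3.55 gives
#'   roughly 11.7-fold).
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  dd <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-dd)
}
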