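#' @importFrom stats coef cor lm median pf pnorm prcomp pt qnorm quantile
#'   rbinom rnorm runif sd setNames var rlnorm fisher.test complete.cases
#' @importFrom utils write.table read.table head tail
#' @import data.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# numeric check that also rejects NA
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x > 0
}

assert_prob <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_config(field, sprintf("must be a number in [%g, %g]", lo, hi))
  invisible(x)
}

#' Significance threshold from the number of SNPs tested
#'
#' Genome-wide p-value cutoff as `alpha / n_snps` (Bonferroni-style across all
#' SNPs, not per protein), reported at three significant figures as is
#' conventional for printed thresholds.
#'
#' @param n_snps number of SNPs analyzed (after merging array and imputed sets).
#' @param alpha family-wise error rate, default 0.05.
#' @return the threshold, rounded to 3 significant figures.
#' @examples
#' significance_threshold(1671387)   # 2.99e-08
#' @export
significance_threshold <- function(n_snps, alpha = 0.05) {
  if (!is_count(n_snps)) stop_config("n_snps", "must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha", "must be in (0,1)")
  signif(alpha / n_snps, 3)
}
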