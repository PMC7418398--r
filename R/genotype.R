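#' Genotype container and variant-level quality control
#'
#' A `genotype_matrix` stores additive dosages (alt-allele counts 0/1/2, NA =
#' missing) for samples x variants together with variant metadata. QC follows
#' the usual array-genotyping conventions: drop variants with call rate below
#' 0.99, minor allele frequency below 0.01, or exact Hardy-Weinberg p below
#' 1e-4; sex chromosomes are out of scope (autosomes only).
#'
#' @name genotype
NULL

#' Construct a genotype matrix
#'
#' @param dosage numeric matrix, samples x variants, entries in \{0,1,2\} or NA.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `rsid`,
#'   `ref`, `alt`; positions must be sorted within chromosome and rsIDs unique.
#' @param samples character vector of sample IDs (defaults to rownames).
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  variants <- as.data.table(variants)
  req <- c("chrom", "pos", "rsid", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants), " variant records")
  if (anyDuplicated(variants$rsid)) stop("rsIDs must be unique")
  unsorted <- variants[, any(diff(pos) < 0), by = chrom]$V1
  if (any(unsorted)) stop("variant positions must be sorted within chromosome")
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad)) stop("dosages must be in {0,1,2} or NA")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  rownames(dosage) <- samples
  colnames(dosage) <- variants$rsid
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Variant call rate
#'
#' Fraction of samples with a non-missing genotype. Removal in QC happens iff
#' the rate is strictly below the threshold, so 0.99 itself is kept.
#'
#' @param dosage numeric vector of dosages for one variant (NA = missing).
#' @export
call_rate <- function(dosage) {
  if (!length(dosage)) stop("call_rate of a variant with zero samples")
  mean(!is.na(dosage))
}

#' Minor allele frequency
#'
#' `min(p, 1-p)` with p the alt-allele frequency among non-missing genotypes.
#'
#' @inheritParams call_rate
#' @export
maf <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) stop("MAF of a variant with zero called samples")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Classical exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts (same parity,
#' same allele totals) whose conditional probability does not exceed that of
#' the observed configuration. Plain exact convention (no mid-p). A chi-square
#' alternative is available via `method = "chisq"`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @param method `"exact"` (default) or `"chisq"` (1 df, no continuity correction).
#' @return two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("HWE test requires at least one sample")
  if (method == "chisq") {
    p <- (2 * n_aa + n_ab) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  n_a <- 2 * n_aa + n_ab          # copies of the A allele
  n_minor <- min(n_a, 2 * n - n_a)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each possible het count, up to a constant
  lp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    h * log(2) - lfactorial(hom_minor) - lfactorial(h) - lfactorial(hom_major)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over samples non-missing in both
#' variants (pairwise-complete; no imputation).
#'
#' @param a,b dosage vectors of equal length.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Variant-level QC filter
#'
#' Removes variants failing call rate, MAF or exact HWE thresholds, in that
#' order of accounting (a variant failing several criteria is counted under
#' the first). Filtering is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate keep iff call rate >= this (default 0.99).
#' @param min_maf keep iff MAF >= this (default 0.01).
#' @param min_hwe_p keep iff exact HWE p >= this (default 1e-4).
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (data.table of per-criterion removal counts).
#' @export
qc_filter <- function(gm, min_call_rate = 0.99, min_maf = 0.01,
                      min_hwe_p = 1e-4) {
  for (v in c(min_call_rate, min_maf, min_hwe_p))
    if (v <= 0 || v >= 1) stop_config("qc threshold", "must lie in (0,1)")
  d <- gm$dosage
  cr <- colMeans(!is.na(d))
  mafs <- apply(d, 2, maf)
  hwe <- apply(d, 2, function(col) {
    col <- col[!is.na(col)]
    hwe_exact_p(sum(col == 0), sum(col == 1), sum(col == 2))
  })
  fail_cr <- cr < min_call_rate
  fail_maf <- !fail_cr & mafs < min_maf
  fail_hwe <- !fail_cr & !fail_maf & hwe < min_hwe_p
  keep <- !(fail_cr | fail_maf | fail_hwe)
  report <- data.table(
    criterion = c("call_rate", "maf", "hwe", "kept"),
    threshold = c(min_call_rate, min_maf, min_hwe_p, NA),
    n = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe), sum(keep)))
  list(genotypes = subset_variants(gm, keep), report = report)
}

subset_variants <- function(gm, keep) {
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$variants[keep], gm$samples)
}

#' Sliding-window LD pruning
#'
#' Windows of `window` variants advanced by `step` variants, per chromosome.
#' Within a window, while any retained pair has r-squared above the threshold,
#' the pair member with the lower MAF is removed (ties: the later position).
#' Violating pairs are visited in (left index, right index) order, which makes
#' the procedure deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in variants (default 50).
#' @param step step size in variants (default 5).
#' @param r2 r-squared threshold (default 0.8); pairs strictly above it conflict.
#' @return logical vector over variants: TRUE = retained ("independent locus
#'   markers").
#' @export
ld_prune <- function(gm, window = 50, step = 5, r2 = 0.8) {
  if (!is_count(window) || !is_count(step) || step > window)
    stop_config("window/step", "window and step must be positive with step <= window")
  if (r2 <= 0 || r2 > 1) stop_config("r2", "must be in (0,1]")
  d <- gm$dosage
  mafs <- apply(d, 2, maf)
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == chr)
    starts <- seq(1L, max(1L, length(idx)), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      repeat {
        ret <- win[keep[win]]
        if (length(ret) < 2) break
        removed <- FALSE
        for (ii in seq_len(length(ret) - 1L)) {
          for (jj in (ii + 1L):length(ret)) {
            a <- ret[ii]; b <- ret[jj]
            r <- ld_r2(d[, a], d[, b])
            if (!is.na(r) && r > r2) {
              drop <- if (mafs[a] < mafs[b]) a
                      else if (mafs[b] < mafs[a]) b
                      else max(a, b)     # tie: later position goes
              keep[drop] <- FALSE
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
        if (!removed) break
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  keep
}

#' Genotype principal component analysis
#'
#' PCA of the column-standardized dosage matrix (monomorphic variants are
#' skipped). Used both for covariates in the association scan (top three PCs)
#' and for population-outlier screening.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components to return (default 3).
#' @param outlier_sd flag a sample as outlier when |score| exceeds this many
#'   SDs on any of the top `k` PCs (default 6).
#' @return list with `scores` (samples x k), `sdev`, and `outliers` (logical).
#' @export
genotype_pca <- function(gm, k = 3, outlier_sd = 6) {
  d <- gm$dosage
  d[is.na(d)] <- matrix(colMeans(d, na.rm = TRUE),
                        nrow(d), ncol(d), byrow = TRUE)[is.na(d)]
  sds <- apply(d, 2, sd)
  z <- scale(d[, sds > 0, drop = FALSE])
  k <- min(k, ncol(z), nrow(z) - 1L)
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$samples
  lim <- outlier_sd * apply(scores, 2, sd)
  out <- rowSums(abs(scores) > rep(lim, each = nrow(scores))) > 0
  list(scores = scores, sdev = pc$sdev[seq_len(k)], outliers = out)
}
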