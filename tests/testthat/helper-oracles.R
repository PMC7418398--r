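# Independent brute-force oracles used to cross-check the statistical engine.
# These deliberately re-derive each quantity from first principles along a
# different code path than the package implementation.

# Exact HWE p by enumeration of genotype configurations (a, h, b) compatible
# with the observed sample size and allele counts; P(a,h,b) proportional to
# the multinomial coefficient times 2^h.
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  configs <- list()
  for (a in 0:n) for (h in 0:(n - a)) {
    b <- n - a - h
    if (2 * a + h == n_a) configs[[length(configs) + 1L]] <- c(a, h, b)
  }
  logw <- vapply(configs, function(g)
    lgamma(n + 1) - lgamma(g[1] + 1) - lgamma(g[2] + 1) - lgamma(g[3] + 1) +
      g[2] * log(2), numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- which(vapply(configs, function(g)
    all(g == c(n_aa, n_ab, n_bb)), logical(1)))
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration with binomial coefficients (no dhyper, no fisher.test).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[match(a, ks)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Greedy windowed LD pruning, re-implemented directly from the rule text.
oracle_ld_prune <- function(dosage, variants, window, step, r2thr, mafs) {
  keep <- rep(TRUE, nrow(variants))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    s <- 1L
    repeat {
      win <- idx[s:min(s + window - 1L, length(idx))]
      repeat {
        ret <- win[keep[win]]
        if (length(ret) < 2) break
        viol <- NULL
        for (ii in seq_len(length(ret) - 1L)) {
          for (jj in (ii + 1L):length(ret)) {
            r <- suppressWarnings(cor(dosage[, ret[ii]], dosage[, ret[jj]],
                                      use = "pairwise.complete.obs"))
            if (!is.na(r) && r^2 > r2thr) { viol <- c(ret[ii], ret[jj]); break }
          }
          if (!is.null(viol)) break
        }
        if (is.null(viol)) break
        a <- viol[1]; b <- viol[2]
        drop <- if (mafs[a] < mafs[b]) a else if (mafs[b] < mafs[a]) b else max(a, b)
        keep[drop] <- FALSE
      }
      if (s + window - 1L >= length(idx)) break
      s <- s + step
    }
  }
  keep
}

# Hotspot discovery re-implemented from the seed/extension rule text.
oracle_hotspots <- function(records, rho, max_gap = 1e6, min_abs_rho = 0.5) {
  cross_ok <- function(a, b, allow_self) {
    if (allow_self && length(intersect(a, b))) return(TRUE)
    best <- -Inf
    for (x in a) for (y in b) if (x != y) best <- max(best, abs(rho[x, y]))
    is.finite(best) && best > min_abs_rho
  }
  res <- list()
  for (chr in unique(records$chrom)) {
    rc <- records[records$chrom == chr, ]
    agg <- aggregate(protein ~ rsid + pos, rc, function(x) list(unique(x)))
    agg <- agg[order(agg$pos, agg$rsid), ]
    prots <- lapply(agg$protein, function(x) x[[1]])
    n <- nrow(agg)
    used <- rep(FALSE, n)
    i <- 1L
    while (i < n) {
      if (used[i]) { i <- i + 1L; next }
      j <- i + 1L
      while (j <= n && used[j]) j <- j + 1L
      if (j > n) break
      if (!(agg$pos[j] - agg$pos[i] < max_gap &&
            cross_ok(prots[[i]], prots[[j]], FALSE))) { i <- i + 1L; next }
      mem <- c(i, j)
      repeat {
        grew <- FALSE
        r <- max(mem); k <- r + 1L
        while (k <= n && used[k]) k <- k + 1L
        if (k <= n && agg$pos[k] - agg$pos[r] <= max_gap &&
            cross_ok(prots[[k]], prots[[r]], TRUE)) { mem <- c(mem, k); grew <- TRUE }
        l <- min(mem); k <- l - 1L
        while (k >= 1L && used[k]) k <- k - 1L
        if (k >= 1L && agg$pos[l] - agg$pos[k] <= max_gap &&
            cross_ok(prots[[k]], prots[[l]], TRUE)) { mem <- c(mem, k); grew <- TRUE }
        if (!grew) break
      }
      mem <- sort(mem)
      used[mem] <- TRUE
      res[[length(res) + 1L]] <- list(chrom = chr, members = agg$rsid[mem])
      i <- max(mem) + 1L
    }
  }
  res
}

# O(n*m) interval stabbing: label every variant against every feature row.
oracle_stab <- function(variants, features) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(features))) {
      if (variants$chrom[i] == features$chrom[j] &&
          variants$pos[i] >= features$start[j] &&
          variants$pos[i] <= features$end[j])
        out[[length(out) + 1L]] <- data.frame(
          rsid = variants$rsid[i], row = j,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(rsid = character(), row = integer()))
  do.call(rbind, out)
}
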