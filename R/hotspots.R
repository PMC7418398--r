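#' Protein co-expression correlation and pQTL hotspot discovery
#'
#' Hotspots are genomic intervals where pQTLs for multiple correlated proteins
#' cluster. Scanning position-sorted significant variants per chromosome: two
#' neighboring variants seed a hotspot when they are associated with different
#' proteins, lie strictly less than `max_gap` apart, and some cross-pair
#' protein pair has |Spearman rho| above `min_abs_rho`. The hotspot is then
#' extended with the next neighboring variant while it lies within `max_gap`
#' of the nearest member (inclusive) and correlates (|rho| > `min_abs_rho`)
#' with a protein of that nearest member. Extension is bidirectional.
#'
#' @name hotspots
NULL

#' Spearman correlation matrix over proteins
#'
#' Average-rank ties; pairwise-complete samples; p-values from the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param proteins a `protein_matrix` or a proteins x samples numeric matrix.
#' @return list with `rho` and `p` matrices plus summary counts: number of
#'   pairs with |rho| > 0.5 and > 0.8, and the median rho among pairs with
#'   p < 0.05.
#' @export
spearman_matrix <- function(proteins) {
  m <- if (inherits(proteins, "protein_matrix")) proteins$conc else proteins
  rho <- suppressWarnings(
    cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  npair <- tcrossprod(!is.na(m))
  tstat <- rho * sqrt((npair - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), pmax(npair - 2, 1), lower.tail = FALSE)
  diag(p) <- 0
  up <- upper.tri(rho)
  list(rho = rho, p = p,
       n_abs_gt_0.5 = sum(abs(rho[up]) > 0.5, na.rm = TRUE),
       n_abs_gt_0.8 = sum(abs(rho[up]) > 0.8, na.rm = TRUE),
       median_rho_significant = median(rho[up][p[up] < 0.05], na.rm = TRUE))
}

# |rho| between any protein of set a and any protein of set b above the
# cutoff. Same-protein pairs (rho = 1 with itself) count only when
# allow_self = TRUE: hotspot seeds require genuinely different proteins,
# whereas during extension two nearby QTLs of one protein may chain.
cross_correlated <- function(rho, a, b, min_abs_rho, allow_self = FALSE) {
  if (allow_self && length(intersect(a, b))) return(TRUE)
  pairs <- abs(rho[a, b, drop = FALSE])
  for (p in intersect(a, b)) pairs[p, p] <- NA
  any(pairs > min_abs_rho, na.rm = TRUE)
}

#' Find QTL hotspots
#'
#' @param records significant-association table with columns `rsid`, `chrom`,
#'   `pos`, `protein` (a [pqtl_scan()] `records` table, or an external QTL
#'   table with `protein` holding the regulated gene's quantified protein).
#' @param corr a [spearman_matrix()] result (or a bare rho matrix) covering
#'   every protein in `records`.
#' @param max_gap distance rule in bp (default 1e6): seeds require a gap
#'   strictly below it, extension allows equality.
#' @param min_abs_rho correlation rule (default 0.5, strict >).
#' @param direction `"both"` (default) extends the seed in both directions,
#'   `"downstream"` only to the right.
#' @return data.table of hotspots: id, chrom, start, end, n_variants,
#'   n_proteins, variants and proteins (semicolon-joined, variants in position
#'   order), plus a `members` list column.
#' @export
find_hotspots <- function(records, corr, max_gap = 1e6, min_abs_rho = 0.5,
                          direction = c("both", "downstream")) {
  direction <- match.arg(direction)
  rho <- if (is.list(corr)) corr$rho else corr
  records <- as.data.table(records)
  missing <- setdiff(unique(records$protein), rownames(rho))
  if (length(missing))
    stop("proteins absent from the correlation matrix: ",
         paste(missing, collapse = ", "))
  out <- list()
  hid <- 0L
  for (chr in unique(records$chrom)) {
    # one row per variant, with its protein set
    vt <- records[chrom == chr,
                  .(proteins = list(unique(protein))), by = .(rsid, pos)]
    setorder(vt, pos, rsid)
    n <- nrow(vt)
    used <- rep(FALSE, n)
    i <- 1L
    while (i < n) {
      if (used[i]) { i <- i + 1L; next }
      j <- i + 1L
      while (j <= n && used[j]) j <- j + 1L
      if (j > n) break
      pi_ <- vt$proteins[[i]]; pj <- vt$proteins[[j]]
      # seed: some cross-variant pair of *different* proteins correlates
      # (cross_correlated excludes same-protein pairs, so two variants
      # regulating only one common protein can never seed)
      seed_ok <- vt$pos[j] - vt$pos[i] < max_gap &&
        cross_correlated(rho, pi_, pj, min_abs_rho)
      if (!seed_ok) { i <- i + 1L; next }
      members <- c(i, j)
      repeat {
        extended <- FALSE
        # downstream candidate: next unused variant after the right edge
        right <- max(members)
        k <- right + 1L
        while (k <= n && used[k]) k <- k + 1L
        if (k <= n &&
            vt$pos[k] - vt$pos[right] <= max_gap &&
            cross_correlated(rho, vt$proteins[[k]], vt$proteins[[right]],
                             min_abs_rho, allow_self = TRUE)) {
          members <- c(members, k); extended <- TRUE
        }
        if (direction == "both") {
          left <- min(members)
          k <- left - 1L
          while (k >= 1L && used[k]) k <- k - 1L
          if (k >= 1L &&
              vt$pos[left] - vt$pos[k] <= max_gap &&
              cross_correlated(rho, vt$proteins[[k]], vt$proteins[[left]],
                               min_abs_rho, allow_self = TRUE)) {
            members <- c(members, k); extended <- TRUE
          }
        }
        if (!extended) break
      }
      members <- sort(members)
      used[members] <- TRUE
      hid <- hid + 1L
      out[[hid]] <- data.table(
        id = sprintf("hotspot_%03d", hid), chrom = chr,
        start = vt$pos[members[1]], end = vt$pos[members[length(members)]],
        n_variants = length(members),
        n_proteins = uniqueN(unlist(vt$proteins[members])),
        variants = paste(vt$rsid[members], collapse = ";"),
        proteins = paste(sort(unique(unlist(vt$proteins[members]))),
                         collapse = ";"),
        members = list(vt$rsid[members]))
      i <- max(members) + 1L
    }
  }
  if (!length(out))
    return(data.table(id = character(), chrom = character(), start = integer(),
                      end = integer(), n_variants = integer(),
                      n_proteins = integer(), variants = character(),
                      proteins = character(), members = list()))
  rbindlist(out)
}

#' Majority annotation of a hotspot
#'
#' Terms annotated to at least half (ceiling) of the hotspot's member
#' proteins, and always to at least two of them, so a term carried by a
#' single protein never annotates a two-protein hotspot.
#'
#' @param hotspot_proteins character vector of member protein IDs.
#' @param term_map data.frame with columns `protein`, `term` (e.g. GO
#'   annotation export).
#' @return character vector of terms (possibly empty).
#' @export
annotate_hotspot <- function(hotspot_proteins, term_map) {
  term_map <- as.data.table(term_map)
  need <- max(2, ceiling(length(hotspot_proteins) / 2))
  tm <- unique(term_map[protein %in% hotspot_proteins])
  cnt <- tm[, .N, by = term]
  sort(cnt[N >= need]$term)
}

#' Enrichment of shared hotspots among highly correlated protein pairs
#'
#' 2x2 Fisher exact test of \{|rho| > 0.5 vs not\} x \{pair shares >= 1
#' hotspot vs not\} over all protein pairs in the correlation matrix.
#'
#' @param corr a [spearman_matrix()] result.
#' @param hotspots a [find_hotspots()] table.
#' @param min_abs_rho high-correlation cutoff (default 0.5).
#' @return list(table, odds_ratio, p).
#' @export
shared_hotspot_enrichment <- function(corr, hotspots, min_abs_rho = 0.5) {
  rho <- corr$rho
  prots <- rownames(rho)
  shared <- matrix(FALSE, length(prots), length(prots),
                   dimnames = list(prots, prots))
  for (k in seq_len(nrow(hotspots))) {
    hp <- intersect(strsplit(hotspots$proteins[k], ";", fixed = TRUE)[[1]],
                    prots)
    if (length(hp) > 1) shared[hp, hp] <- TRUE
  }
  up <- upper.tri(rho)
  high <- abs(rho[up]) > min_abs_rho
  sh <- shared[up]
  tab <- matrix(c(sum(high & sh), sum(high & !sh),
                  sum(!high & sh), sum(!high & !sh)),
                2, 2, byrow = TRUE,
                dimnames = list(correlated = c("high", "low"),
                                hotspot = c("shared", "not_shared")))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' eQTL hotspots from an external QTL summary table
#'
#' Applies the identical hotspot algorithm to an externally supplied QTL table
#' after restricting it to variants genotyped and genes/proteins quantified in
#' this study.
#'
#' @param qtl data.frame with columns `rsid`, `trait` (regulated gene or
#'   protein ID); positions are taken from `gm`.
#' @param gm a [genotype_matrix()] supplying variant coordinates.
#' @param corr a [spearman_matrix()] result over this study's proteins.
#' @param ... passed to [find_hotspots()].
#' @export
find_eqtl_hotspots <- function(qtl, gm, corr, ...) {
  qtl <- as.data.table(qtl)
  rho <- if (is.list(corr)) corr$rho else corr
  i <- match(qtl$rsid, gm$variants$rsid)
  qtl <- qtl[!is.na(i) & trait %in% rownames(rho)]
  if (!nrow(qtl))
    return(find_hotspots(data.table(rsid = character(), chrom = character(),
                                    pos = integer(), protein = character()),
                         corr, ...))
  i <- match(qtl$rsid, gm$variants$rsid)
  recs <- data.table(rsid = qtl$rsid, chrom = gm$variants$chrom[i],
                     pos = gm$variants$pos[i], protein = qtl$trait)
  find_hotspots(recs, corr, ...)
}
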