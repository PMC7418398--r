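#' Regulatory-region mapping and genomic-region enrichment
#'
#' Variants are mapped by position to transcriptional regulatory regions
#' (Ensembl-regulatory-build style feature classes) and to gene features
#' (UTR/CDS/exon/intron) from a GTF. Enrichment of a protein's pQTL variants
#' in a gene's features is a two-sided Fisher exact test against the post-QC
#' tested-SNP universe, Bonferroni-corrected over all tests performed.
#' All internal coordinates are 1-based inclusive; BED input (0-based
#' half-open) is converted on ingest.
#'
#' @name regions
NULL

REGULATORY_CLASSES <- c("CTCF_binding_site", "enhancer", "open_chromatin",
                        "promoter", "promoter_flanking", "TF_binding_site")

#' Read regulatory regions from BED
#'
#' BED with the feature class in the 4th (name) column. Coordinates are
#' converted from 0-based half-open to 1-based inclusive.
#'
#' @param path BED file.
#' @return data.table with columns chrom, start, end, class.
#' @export
read_regulatory_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   class = gr$name)
  bad <- setdiff(unique(dt$class), REGULATORY_CLASSES)
  if (length(bad))
    stop("unknown regulatory feature class(es): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(REGULATORY_CLASSES, collapse = ", "))
  dt
}

#' Read gene models from GTF
#'
#' Keeps gene/exon/CDS/UTR lines; introns are derived as the gene span minus
#' the exon union (gene-level union across transcripts).
#'
#' @param path GTF file with attributes `gene_id` and `gene_type`
#'   (`protein_coding` or a non-coding biotype).
#' @return list with `genes` (gene_id, biotype, chrom, start, end) and
#'   `features` (gene_id, feature in UTR/CDS/exon/intron, chrom, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   gene_type = gr$gene_type)
  genes <- dt[type == "gene",
              .(gene_id, biotype = gene_type, chrom, start, end)]
  feat <- dt[type %in% c("exon", "CDS", "UTR"),
             .(gene_id, feature = type, chrom, start, end)]
  # introns: per gene, gene span minus exon union
  introns <- rbindlist(lapply(split(seq_len(nrow(genes)), genes$gene_id),
    function(i) {
      g <- genes[i]
      ex <- feat[gene_id == g$gene_id & feature == "exon"]
      span <- IRanges::IRanges(g$start, g$end)
      exu <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
      intr <- IRanges::setdiff(span, exu)
      if (!length(intr)) return(NULL)
      data.table(gene_id = g$gene_id, feature = "intron", chrom = g$chrom,
                 start = IRanges::start(intr), end = IRanges::end(intr))
    }))
  list(genes = genes, features = rbind(feat, introns))
}

# GRanges from (chrom, start, end) columns
as_granges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
}

# overlaps with harmonized sequence levels (quiet on disjoint chromosomes)
overlaps <- function(query, subject) {
  lv <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  GenomicRanges::findOverlaps(query, subject)
}

#' Map variants to regulatory regions
#'
#' A variant hits a region iff its position lies within the interval
#' (inclusive of both ends); multiple hits are allowed.
#'
#' @param variants data.frame with `rsid`, `chrom`, `pos`.
#' @param regions regulatory table from [read_regulatory_bed()] (or any
#'   data.frame with chrom, start, end, class).
#' @return list with `hits` (rsid, class, chrom, start, end per overlap) and
#'   `counts` (variants hit per feature class).
#' @export
map_to_regulatory <- function(variants, regions) {
  variants <- as.data.table(variants)
  regions <- as.data.table(regions)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  ov <- overlaps(vgr, as_granges(regions))
  hits <- data.table(rsid = variants$rsid[S4Vectors::queryHits(ov)],
                     class = regions$class[S4Vectors::subjectHits(ov)],
                     chrom = regions$chrom[S4Vectors::subjectHits(ov)],
                     start = regions$start[S4Vectors::subjectHits(ov)],
                     end = regions$end[S4Vectors::subjectHits(ov)])
  counts <- hits[, .(n_variants = uniqueN(rsid)), by = class]
  list(hits = hits, counts = counts)
}

#' Map variants to gene features
#'
#' Labels each variant per overlapped gene with every feature interval it
#' falls into (a variant can be exonic for one gene and intronic for
#' another); variants overlapping no gene are intergenic.
#'
#' @param variants data.frame with `rsid`, `chrom`, `pos`.
#' @param models output of [read_gene_models()].
#' @return data.table (rsid, gene_id, biotype, feature) with one
#'   `feature = "intergenic"`, `gene_id = NA` row per unmapped variant.
#' @export
map_to_gene_features <- function(variants, models) {
  variants <- as.data.table(variants)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  fo <- overlaps(vgr, as_granges(models$features))
  lab <- data.table(rsid = variants$rsid[S4Vectors::queryHits(fo)],
                    gene_id = models$features$gene_id[S4Vectors::subjectHits(fo)],
                    feature = models$features$feature[S4Vectors::subjectHits(fo)])
  lab <- unique(lab)
  lab[, biotype := models$genes$biotype[match(gene_id, models$genes$gene_id)]]
  go <- overlaps(vgr, as_granges(models$genes))
  mapped <- unique(variants$rsid[S4Vectors::queryHits(go)])
  inter <- variants[!rsid %in% mapped,
                    .(rsid, gene_id = NA_character_, feature = "intergenic",
                      biotype = NA_character_)]
  rbind(lab[, .(rsid, gene_id, feature, biotype)], inter)
}

#' Fisher enrichment of a protein's pQTLs in gene features
#'
#' For each (gene, feature) with at least one pQTL hit, a 2x2 table over the
#' tested-variant universe: \{variant is a pQTL for this protein\} x
#' \{variant lies in this gene feature\}. Two-sided Fisher exact p,
#' Bonferroni-adjusted over all tests performed (across proteins when called
#' through [regulator_enrichment_all()]). A gene is a predicted regulator of
#' the protein when adjusted p < 0.05 and the odds ratio exceeds 1.
#'
#' @param pqtl_rsids rsIDs of the protein's pQTL variants.
#' @param universe data.frame of all tested variants (`rsid`, `chrom`, `pos`).
#' @param models output of [read_gene_models()].
#' @param n_tests total tests for the Bonferroni correction (default: number
#'   of tables computed here).
#' @return data.table with gene_id, feature, a, b, c, d (2x2 counts),
#'   odds_ratio, p, p_adj, significant.
#' @export
regulator_enrichment <- function(pqtl_rsids, universe, models, n_tests = NULL) {
  universe <- as.data.table(universe)
  if (!nrow(universe)) stop("empty tested-variant universe")
  labels <- map_to_gene_features(universe, models)
  labels <- labels[feature != "intergenic"]
  is_pqtl <- universe$rsid %in% pqtl_rsids
  n_p <- sum(is_pqtl)
  n_u <- nrow(universe)
  cand <- unique(labels[rsid %in% pqtl_rsids, .(gene_id, feature)])
  if (!nrow(cand))
    return(data.table(gene_id = character(), feature = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  res <- labels[cand, on = c("gene_id", "feature")][
    , .(in_feat = uniqueN(rsid),
        a = uniqueN(rsid[rsid %in% pqtl_rsids])),
    by = .(gene_id, feature)]
  res[, `:=`(b = n_p - a, c = in_feat - a, d = n_u - n_p - (in_feat - a))]
  ft <- lapply(seq_len(nrow(res)), function(k)
    fisher.test(matrix(c(res$a[k], res$b[k], res$c[k], res$d[k]), 2, 2,
                       byrow = TRUE)))
  res[, odds_ratio := vapply(ft, function(f) unname(f$estimate), numeric(1))]
  res[, p := vapply(ft, function(f) f$p.value, numeric(1))]
  nt <- n_tests %||% nrow(res)
  res[, p_adj := pmin(1, p * nt)]
  res[, significant := p_adj < 0.05 & odds_ratio > 1]
  res[, in_feat := NULL]
  res[]
}

#' Regulator enrichment across all proteins
#'
#' Runs [regulator_enrichment()] per protein and applies one Bonferroni
#' correction over every (protein, gene, feature) test performed.
#'
#' @param records significant-association table ([pqtl_scan()] `records`).
#' @param universe all tested variants (`rsid`, `chrom`, `pos`).
#' @param models output of [read_gene_models()].
#' @export
regulator_enrichment_all <- function(records, universe, models) {
  records <- as.data.table(records)
  per <- lapply(split(records$rsid, records$protein), function(rs)
    regulator_enrichment(unique(rs), universe, models, n_tests = 1L))
  out <- rbindlist(per, idcol = "protein")
  if (!nrow(out)) return(out)
  out[, p_adj := pmin(1, p * nrow(out))]
  out[, significant := p_adj < 0.05 & odds_ratio > 1]
  out[]
}

#' Local/distant counts per genomic region
#'
#' Replicates the multiple-counting convention of per-association region
#' distributions: each (variant, protein) association contributes one count
#' per region assignment, so one variant associated with two proteins can be
#' counted both as a local pQTL in a CDS and as a local pQTL in a promoter.
#' When `labels` carry a `gene_id` and `records` a `gene`, an association is
#' assigned the variant's labels with respect to its own regulated gene where
#' such labels exist, and all of the variant's distinct labels otherwise
#' (distant pQTLs usually sit in unrelated genes).
#'
#' @param records significant-association table with `rsid`, `protein`,
#'   `class` and optionally `gene`.
#' @param labels per-variant region labels (`rsid`, `feature`, optionally
#'   `gene_id`), e.g. from [map_to_gene_features()] or regulatory `hits`
#'   renamed to `feature`.
#' @return data.table of counts per (class, feature).
#' @export
local_distant_region_distribution <- function(records, labels) {
  records <- as.data.table(records)
  labels <- as.data.table(labels)
  if (!nrow(records))
    return(data.table(class = character(), feature = character(),
                      n = integer()))
  gene_aware <- "gene_id" %in% names(labels) && "gene" %in% names(records)
  any_lab <- unique(labels[, .(rsid, feature)])
  per_assoc <- lapply(seq_len(nrow(records)), function(k) {
    r <- records[k]
    lab <- if (gene_aware) {
      own <- labels[rsid == r$rsid & !is.na(gene_id) & gene_id == r$gene]
      if (nrow(own)) unique(own$feature) else any_lab[rsid == r$rsid]$feature
    } else any_lab[rsid == r$rsid]$feature
    if (!length(lab)) return(NULL)
    data.table(class = r$class, feature = lab)
  })
  out <- rbindlist(per_assoc)
  if (!nrow(out))
    return(data.table(class = character(), feature = character(),
                      n = integer()))
  out[, .(n = .N), by = .(class, feature)][order(class, feature)]
}
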