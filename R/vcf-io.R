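#' VCF input/output for genotype matrices
#'
#' Genotypes travel as GT-only VCF with GRCh37-style contig names. Reading is
#' delegated to VariantAnnotation; multi-allelic records are rejected (only
#' biallelic SNPs are supported by the scan).
#'
#' @name vcf_io
NULL

#' Read a GT-only VCF into a genotype matrix
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) != 1L))
    stop("only biallelic variants are supported")
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    rsid = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)))
  gt <- VariantAnnotation::geno(vcf)$GT       # variants x samples
  dosage <- gt_to_dosage(gt)
  genotype_matrix(t(dosage), variants, samples = colnames(gt))
}

gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA, "." = NA)
  d <- map[gt]
  unknown <- !is.na(gt) & !(gt %in% names(map))
  if (any(unknown))
    stop("unsupported GT values: ", paste(unique(gt[unknown]), collapse = ", "))
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as a GT-only VCF
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf_genotypes <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pqtlpipe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (chr in unique(gm$variants$chrom))
    writeLines(sprintf("##contig=<ID=%s>", chr), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  ok <- !is.na(gm$dosage)
  gt[ok] <- gtmap[gm$dosage[ok] + 1L]
  v <- gm$variants
  lines <- paste(v$chrom, v$pos, v$rsid, v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
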