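#' Write a simulated study to disk
#'
#' External formats: GT-only VCF (GRCh37-style contig names), TSV matrices,
#' BED (0-based half-open) for regulatory regions, GTF (1-based inclusive)
#' for gene models, and a JSON ground-truth file.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    peptides = file.path(dir, "peptides.tsv"),
    protein_meta = file.path(dir, "protein_meta.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    regulatory_bed = file.path(dir, "regulatory.bed"),
    genes_gtf = file.path(dir, "genes.gtf"),
    traits = file.path(dir, "traits.tsv"),
    external_qtl = file.path(dir, "external_qtl.tsv"),
    truth = file.path(dir, "truth.json"))
  write_vcf_genotypes(study$genotypes, paths["vcf"])
  fwrite(study$peptides$table, paths["peptides"], sep = "\t", na = "NA",
         quote = FALSE)
  fwrite(study$peptides$meta, paths["protein_meta"], sep = "\t", quote = FALSE)
  fwrite(study$covariates, paths["covariates"], sep = "\t", quote = FALSE)
  write_regulatory_bed(study$annotations$regulatory, paths["regulatory_bed"])
  write_gene_models_gtf(study$annotations$gene_models, paths["genes_gtf"])
  fwrite(study$annotations$traits, paths["traits"], sep = "\t", quote = FALSE)
  fwrite(study$annotations$external_qtl, paths["external_qtl"], sep = "\t",
         quote = FALSE)
  truth <- study$truth
  jsonlite::write_json(
    list(planted = truth$planted, clusters = truth$clusters,
         conc = truth$conc),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Write regulatory regions as BED (4th column = feature class)
#' @param regions data.table with chrom, start, end (1-based inclusive), class.
#' @param path output BED path.
#' @export
write_regulatory_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end),
                               name = regions$class)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write gene models as GTF
#' @param models list(genes, features) as produced by the generator or
#'   [read_gene_models()]; introns are derived on read, not written.
#' @param path output GTF path.
#' @export
write_gene_models_gtf <- function(models, path) {
  feats <- models$features[feature != "intron"]
  genes <- copy(models$genes)[, feature := "gene"]
  dt <- rbind(genes[, .(gene_id, biotype, feature, chrom, start, end)],
              feats[, .(gene_id, feature, chrom, start, end,
                        biotype = models$genes$biotype[
                          match(gene_id, models$genes$gene_id)])],
              use.names = TRUE)
  setorder(dt, chrom, start, gene_id)
  lines <- sprintf(
    '%s\tpqtlpipe\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "%s";',
    dt$chrom, dt$feature, dt$start, dt$end, dt$gene_id, dt$biotype)
  writeLines(lines, path)
  invisible(path)
}
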