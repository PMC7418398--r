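#' End-to-end pipeline orchestration
#'
#' `run_all()` executes the full analysis in study order: TPA quantification,
#' genotype QC + LD pruning + PCA, the additive pQTL scan, protein
#' correlations and hotspot discovery, regulatory-region and gene-feature
#' mapping with regulator enrichment, trait integration and colocalization.
#' Every stage writes a TSV; a JSON manifest records package version, seed
#' and all parameters so a run can be reproduced bit-identically.
#'
#' @name cli_pipeline
NULL

default_params <- function() {
  list(min_call_rate = 0.99, min_maf = 0.01, min_hwe_p = 1e-4,
       prune_window = 50, prune_step = 5, prune_r2 = 0.8,
       n_pcs = 3, scan_threshold = "auto", local_limit = 1e6,
       min_quant_frac = 0.90, hotspot_max_gap = 1e6,
       hotspot_min_abs_rho = 0.5, enrichment_alpha = 0.05,
       coloc_r2 = 0.8, coloc_threshold = NULL, seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with an `inputs:` block of file paths (vcf, peptides,
#' protein_meta, covariates, regulatory_bed, genes_gtf, traits, external_qtl,
#' optional annotation_terms), an `out_dir:`, and an optional `params:` block
#' overriding the built-in defaults.
#'
#' @param path configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$params <- utils::modifyList(default_params(), cfg$params %||% list())
  cfg
}

#' Validate pipeline inputs before any computation
#'
#' Checks file existence, sample-ID concordance across genotypes, peptide
#' areas and covariates (extra samples in the protein side are intersected
#' with a warning; missing covariates are an error), coordinate sanity and
#' the regulatory feature-class vocabulary.
#'
#' @param cfg configuration list ([read_pipeline_config()] output or
#'   equivalent).
#' @param loaded optional list(genotypes, peptides, covariates) of already
#'   parsed inputs, to avoid re-reading large files.
#' @return character vector of warnings (empty when all is clean); errors
#'   abort.
#' @export
validate_inputs <- function(cfg, loaded = NULL) {
  notes <- character(0)
  req <- c("vcf", "peptides", "protein_meta", "covariates")
  for (f in req) {
    p <- cfg$inputs[[f]]
    if (is.null(p) || !file.exists(p))
      stop("missing input file for '", f, "': ", p %||% "<unset>")
  }
  for (f in c("regulatory_bed", "genes_gtf", "traits", "external_qtl",
              "annotation_terms")) {
    p <- cfg$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("missing input file for '", f, "': ", p)
  }
  gm <- loaded$genotypes %||% read_vcf_genotypes(cfg$inputs$vcf)
  pep <- loaded$peptides %||% read_peptide_table(cfg$inputs$peptides)
  cov <- loaded$covariates %||% fread(cfg$inputs$covariates)
  psamp <- attr(pep, "samples")
  extra <- setdiff(psamp, gm$samples)
  if (length(extra))
    notes <- c(notes, paste0("peptide table has ", length(extra),
                             " sample(s) absent from the VCF; intersected"))
  missing_cov <- setdiff(gm$samples, cov$sample)
  if (length(missing_cov))
    stop("covariate table lacks samples: ",
         paste(missing_cov, collapse = ", "))
  if (!is.null(cfg$inputs$regulatory_bed))
    read_regulatory_bed(cfg$inputs$regulatory_bed)   # validates vocabulary
  notes
}

#' Run the full pipeline
#'
#' @param cfg configuration list or path to a YAML config.
#' @return list of stage results (invisibly also written under
#'   `cfg$out_dir`): proteins, qc, pruned, pca, scan, correlations, hotspots,
#'   eqtl_hotspots, regulatory, gene_features, enrichment, distribution,
#'   traits, coloc, summary, manifest.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg$params <- utils::modifyList(default_params(), cfg$params %||% list())
  p <- cfg$params
  out <- cfg$out_dir %||% stop("out_dir not set")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(p$seed)
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                                    sprintf(...)))

  for (f in c("vcf", "peptides", "protein_meta", "covariates")) {
    path <- cfg$inputs[[f]]
    if (is.null(path) || !file.exists(path))
      stop("missing input file for '", f, "': ", path %||% "<unset>")
  }
  gm <- read_vcf_genotypes(cfg$inputs$vcf)
  pep <- read_peptide_table(cfg$inputs$peptides)
  meta <- protein_meta(fread(cfg$inputs$protein_meta))
  cov <- fread(cfg$inputs$covariates)
  notes <- validate_inputs(cfg, loaded = list(genotypes = gm, peptides = pep,
                                              covariates = cov))
  log_stage("load", "%d samples, %d variants, %d peptides",
            length(gm$samples), nrow(gm$variants), nrow(pep))

  # keep only samples present in the genotypes
  keep_cols <- c("peptide_id", "sequence", "protein_ids", gm$samples)
  pep <- peptide_signal_table(pep[, intersect(keep_cols, names(pep)),
                                  with = FALSE])
  proteins <- quantify_matrix(pep, meta)
  write_protein_matrix(proteins, file.path(out, "protein_matrix.tsv"))
  log_stage("quantify", "%d proteins quantified", nrow(proteins$conc))

  qc <- qc_filter(gm, p$min_call_rate, p$min_maf, p$min_hwe_p)
  fwrite(qc$report, file.path(out, "qc_report.tsv"), sep = "\t")
  kept <- ld_prune(qc$genotypes, p$prune_window, p$prune_step, p$prune_r2)
  pruned <- subset_variants(qc$genotypes, kept)
  fwrite(data.table(rsid = pruned$variants$rsid),
         file.path(out, "retained_variants.tsv"), sep = "\t")
  log_stage("qc", "%d variants pass QC, %d retained after LD pruning",
            nrow(qc$genotypes$variants), nrow(pruned$variants))

  pca <- genotype_pca(pruned, k = p$n_pcs)
  fwrite(data.table(sample = rownames(pca$scores), pca$scores,
                    outlier = pca$outliers),
         file.path(out, "pca_scores.tsv"), sep = "\t")

  design <- covariate_design(cov, pca$scores, pruned$samples)
  scan <- pqtl_scan(pruned, proteins, covariates = design,
                    threshold = p$scan_threshold, limit = p$local_limit,
                    min_frac = p$min_quant_frac)
  fwrite(scan$records, file.path(out, "pqtl_records.tsv"), sep = "\t")
  log_stage("scan", "%d significant interactions at p < %.3g",
            nrow(scan$records), scan$threshold)

  elig <- eligible_proteins(proteins, p$min_quant_frac)
  corr <- spearman_matrix(proteins$conc[elig, , drop = FALSE])
  hotspots <- find_hotspots(scan$records, corr, p$hotspot_max_gap,
                            p$hotspot_min_abs_rho)
  if (!is.null(cfg$inputs$annotation_terms) && nrow(hotspots)) {
    terms <- fread(cfg$inputs$annotation_terms)
    hotspots[, annotations := vapply(
      strsplit(proteins, ";", fixed = TRUE),
      function(pr) paste(annotate_hotspot(pr, terms), collapse = ";"),
      character(1))]
  }
  fwrite(hotspots[, !"members"], file.path(out, "hotspots.tsv"), sep = "\t")
  log_stage("hotspots", "%d hotspots", nrow(hotspots))

  eqtl_hotspots <- NULL
  external <- NULL
  if (!is.null(cfg$inputs$external_qtl)) {
    external <- fread(cfg$inputs$external_qtl)
    eqtl_hotspots <- find_eqtl_hotspots(external, pruned, corr,
                                        max_gap = p$hotspot_max_gap,
                                        min_abs_rho = p$hotspot_min_abs_rho)
    fwrite(eqtl_hotspots[, !"members"],
           file.path(out, "eqtl_hotspots.tsv"), sep = "\t")
  }

  sig_variants <- unique(scan$records[, .(rsid, chrom, pos)])
  regulatory <- gene_features <- enrichment <- distribution <- NULL
  if (!is.null(cfg$inputs$regulatory_bed)) {
    reg <- read_regulatory_bed(cfg$inputs$regulatory_bed)
    regulatory <- map_to_regulatory(sig_variants, reg)
    fwrite(regulatory$hits, file.path(out, "regulatory_hits.tsv"), sep = "\t")
  }
  if (!is.null(cfg$inputs$genes_gtf)) {
    models <- read_gene_models(cfg$inputs$genes_gtf)
    gene_features <- map_to_gene_features(sig_variants, models)
    fwrite(gene_features, file.path(out, "gene_feature_labels.tsv"),
           sep = "\t")
    universe <- pruned$variants[, .(rsid, chrom, pos)]
    enrichment <- regulator_enrichment_all(scan$records, universe, models)
    fwrite(enrichment, file.path(out, "regulator_enrichment.tsv"), sep = "\t")
    distribution <- local_distant_region_distribution(scan$records,
                                                      gene_features)
    fwrite(distribution, file.path(out, "region_distribution.tsv"),
           sep = "\t")
    log_stage("regions", "%d enrichment tests, %d significant",
              nrow(enrichment), sum(enrichment$significant %||% FALSE))
  }

  traits <- NULL
  if (!is.null(cfg$inputs$traits)) {
    catalog <- fread(cfg$inputs$traits)
    traits <- map_traits(scan$records, catalog)
    fwrite(traits$triples, file.path(out, "trait_triples.tsv"), sep = "\t")
    log_stage("traits", "%d variants mapped to %d traits",
              traits$n_variants, traits$n_traits)
  }

  coloc <- NULL
  if (!is.null(external) && nrow(scan$records)) {
    thr <- p$coloc_threshold %||% scan$threshold
    coloc <- colocalize_all(scan$records, external, pruned, proteins,
                            covariates = design, threshold = thr,
                            r2_min = p$coloc_r2)
    fwrite(coloc, file.path(out, "colocalization.tsv"), sep = "\t")
    log_stage("coloc", "%d candidate pairs, %d colocalized",
              nrow(coloc), sum(coloc$colocalized))
  }

  summary <- c(scan$summary,
               list(n_hotspots = nrow(hotspots),
                    n_trait_triples = if (is.null(traits)) NA_integer_
                                      else nrow(traits$triples),
                    n_colocalized = if (is.null(coloc)) NA_integer_
                                    else sum(coloc$colocalized),
                    n_variants_tested = nrow(pruned$variants),
                    threshold = scan$threshold))
  manifest <- list(package = "pqtlpipe",
                   version = as.character(utils::packageVersion("pqtlpipe")),
                   params = p, inputs = cfg$inputs, notes = notes,
                   summary = summary)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(proteins = proteins, qc = qc, pruned = pruned, pca = pca,
                 scan = scan, correlations = corr, hotspots = hotspots,
                 eqtl_hotspots = eqtl_hotspots, regulatory = regulatory,
                 gene_features = gene_features, enrichment = enrichment,
                 distribution = distribution, traits = traits, coloc = coloc,
                 summary = summary, manifest = manifest))
}
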