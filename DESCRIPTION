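Package: pqtlpipe
Title: Genome-Wide Protein Quantitative Trait Locus Mapping from DIA Proteomics
Version: 0.1.0
Authors@R:
    person("pQTL", "Pipeline Maintainers", email = "maintainers@pqtlpipe.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide protein quantitative
    trait locus (pQTL) mapping in human tissue cohorts. Implements label-free
    absolute protein quantification from peptide-level DIA MS2 peak areas via
    the total protein approach (TPA) with proportional redistribution of
    shared-peptide signal; variant-level genotype quality control (call rate,
    minor allele frequency, exact Hardy-Weinberg test), sliding-window LD
    pruning and genotype PCA; an additive linear-model association scan with
    demographic and principal-component covariates and a genome-wide
    Bonferroni-style threshold; detection of genomic hotspots of pQTLs over
    correlated proteins; mapping of variants to transcriptional regulatory
    regions and gene features with Fisher-exact regulator enrichment;
    rsID-based variant-trait integration; and LD plus conditional-analysis
    colocalization of pQTL against external eQTL/GWAS summaries. A synthetic
    data generator with known ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
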