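# The packaged toy fixture: 100 samples x 500 SNPs x 50 proteins with two
# planted co-regulated clusters (variants 10-12 and 150-151), two local
# effects, and default QC-clean genotypes. Generated in code at test time;
# its pipeline summary counts were frozen after a hand audit of one run
# (10 planted associations plus deterministic LD proxies at the 1e-4
# genome-wide threshold; the two clusters surface as the two hotspots).
toy_config <- function(seed = 42) {
  pe <- rbind(
    data.frame(
      variant = c(10, 11, 12, 150, 151, 300, 420),
      protein = c(1, 2, 3, 10, 11, 20, 21),
      beta = 1.5,
      class = c("local", "distant", "distant", "distant", "distant",
                "local", "distant")),
    data.frame(variant = c(10, 10, 150), protein = c(2, 3, 11),
               beta = 1.5, class = "distant"))
  pqtlpipe::sim_config(
    n_samples = 100, n_variants = 500, n_proteins = 50,
    maf_range = c(0.1, 0.5), ld_block_size = 20, ld_decay = 0.6,
    n_chrom = 5, noise_sd = 0.5, planted_effects = pe,
    missing_protein_rate = 0.02, seed = seed)
}

toy_pipeline_config <- function(dir, seed = 42) {
  paths <- pqtlpipe::write_simulation(
    pqtlpipe::simulate_study(toy_config(seed)), file.path(dir, "in"))
  list(inputs = as.list(paths[setdiff(names(paths), "truth")]),
       out_dir = file.path(dir, "out"),
       params = list(seed = seed))
}

toy_expected_summary <- list(
  n_interactions = 13L, n_variants = 9L, n_local_variants = 2L,
  n_distant_variants = 8L, n_proteins = 9L, n_hotspots = 2L,
  n_variants_tested = 500L, threshold = 1e-4)
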