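# Small fixtures built in code.

# peptide table from a compact spec list: each element
# list(proteins = "A" or "A;B", areas = named-by-sample numeric vector)
make_peptides <- function(rows, samples = "s1") {
  if (!length(rows)) {
    dt <- data.table::data.table(peptide_id = character(),
                                 sequence = character(),
                                 protein_ids = character())
    for (s in samples) dt[[s]] <- numeric()
    return(peptide_signal_table(dt))
  }
  dt <- data.table::rbindlist(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    areas <- rep(NA_real_, length(samples))
    names(areas) <- samples
    areas[names(r$areas)] <- r$areas
    c(list(peptide_id = sprintf("pep%03d", i),
           sequence = paste0("PEPTIDE", i, "K"),
           protein_ids = r$proteins),
      as.list(areas))
  }))
  peptide_signal_table(dt)
}

make_meta <- function(proteins, mass = 5e4, chrom = "chr1",
                      start = 1e5, end = 2e5) {
  n <- length(proteins)
  protein_meta(data.frame(
    protein = proteins, gene = paste0("G_", proteins),
    chrom = rep_len(chrom, n), start = rep_len(start, n),
    end = rep_len(end, n), mass = rep_len(mass, n)))
}

# genotype matrix straight from a dosage matrix, one chromosome,
# positions 10 kb apart
make_gm <- function(dosage, chrom = "chr1", pos = NULL) {
  m <- ncol(dosage)
  variants <- data.frame(
    chrom = rep_len(chrom, m),
    pos = pos %||% (seq_len(m) * 10000L),
    rsid = sprintf("rs%04d", seq_len(m)),
    ref = "A", alt = "G")
  pqtlpipe::genotype_matrix(dosage, variants)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# two planted co-regulated clusters on separate chromosomes: three adjacent
# variants each, driving a correlated trio of proteins (one shared strong
# variant per cluster plus variant-specific effects)
hotspot_sim <- function(seed, beta = 1.5) {
  pe <- data.frame(
    variant = c(5, 5, 5, 6, 7,  25, 25, 25, 26, 27),
    protein = c(1, 2, 3, 2, 3,  4, 5, 6, 5, 6),
    beta = beta, class = "distant")
  cfg <- pqtlpipe::sim_config(
    n_samples = 287, n_variants = 40, n_proteins = 8,
    ld_block_size = 20, ld_decay = 0.5, n_chrom = 2,
    maf_range = c(0.2, 0.5), noise_sd = 0.5,
    planted_effects = pe, missing_protein_rate = 0, seed = seed)
  pqtlpipe::simulate_study(cfg)
}

# quick protein_matrix wrapper around a proteins x samples matrix
make_pm <- function(conc, meta = NULL) {
  meta <- meta %||% make_meta(rownames(conc))
  structure(list(conc = conc, meta = meta, log = data.table::data.table()),
            class = "protein_matrix")
}
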