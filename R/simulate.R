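#' Synthetic cohort generator with known ground truth
#'
#' Emulates the data structure of a genome-wide liver pQTL study: a cohort of
#' a few hundred donors genotyped at thousands of autosomal SNPs with a
#' realistic MAF spectrum, Hardy-Weinberg genotypes and block LD; a proteome
#' of O(1000) absolutely quantified proteins with planted local/distant
#' genetic effects, demographic covariate effects, correlated protein
#' clusters and missing values; peptide-level MS2 tables whose TPA round trip
#' recovers the true concentrations exactly; and annotation/trait/external-QTL
#' files for the downstream stages. Fixed seed gives bit-identical output.
#'
#' Genotypes use a Gaussian-copula haplotype model: within an LD block the
#' latent normals follow an AR(1) process with correlation `ld_decay^|i-j|`,
#' thresholded at the allele frequency quantile, so adjacent-variant LD is
#' tunable for pruning and colocalization tests. Ethnicity acts on protein
#' means only (categorical covariate), not on genotype structure.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults state the emulated cohort: 287 samples, a desk-scaled SNP panel,
#' 1344 quantifiable proteins, log-normal baseline abundances, and residual
#' noise of one protein-SD unit.
#'
#' @param n_samples cohort size (default 287).
#' @param n_variants number of autosomal SNPs (default 5000; the study scale
#'   of O(10^6) is downscaled to keep desk runs in minutes).
#' @param n_proteins number of quantifiable proteins (default 1344).
#' @param maf_range allele-frequency bounds in (0, 0.5] (default 0.05-0.5).
#' @param ld_block_size variants per LD block (default 20).
#' @param ld_decay AR(1) latent correlation in \[0,1) between adjacent
#'   variants of a block (default 0.9; adjacent dosage r^2 around 0.7).
#' @param n_chrom chromosomes to spread blocks over (default 22).
#' @param planted_effects data.frame(variant, protein, beta, class) of true
#'   effects; `variant`/`protein` are indices, `beta` in protein-SD units,
#'   `class` is `"local"` or `"distant"` and controls where the protein's
#'   gene is placed relative to the variant.
#' @param gender_effect_sd,ethnicity_effect_sd SDs of per-protein covariate
#'   mean shifts (default 0.2 each).
#' @param noise_sd residual SD of protein levels (default 1).
#' @param shared_peptide_fraction fraction of proteins carrying a shared
#'   peptide with a random partner (default 0.3).
#' @param missing_protein_rate MCAR missingness of protein values, at most
#'   0.1 so every protein stays above the 90% quantifiability rule
#'   (default 0.02).
#' @param intercept_meanlog,intercept_sdlog log-normal baseline abundance
#'   parameters in pmol/mg (defaults 2 and 0.5: median ~7.4 pmol/mg).
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 287, n_variants = 5000, n_proteins = 1344,
                       maf_range = c(0.05, 0.5), ld_block_size = 20,
                       ld_decay = 0.9, n_chrom = 22,
                       planted_effects = NULL,
                       gender_effect_sd = 0.2, ethnicity_effect_sd = 0.2,
                       noise_sd = 1, shared_peptide_fraction = 0.3,
                       missing_protein_rate = 0.02,
                       intercept_meanlog = 2, intercept_sdlog = 0.5,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_variants = n_variants,
              n_proteins = n_proteins, maf_range = maf_range,
              ld_block_size = ld_block_size, ld_decay = ld_decay,
              n_chrom = n_chrom,
              planted_effects = planted_effects %||%
                data.frame(variant = integer(), protein = integer(),
                           beta = numeric(), class = character()),
              gender_effect_sd = gender_effect_sd,
              ethnicity_effect_sd = ethnicity_effect_sd,
              noise_sd = noise_sd,
              shared_peptide_fraction = shared_peptide_fraction,
              missing_protein_rate = missing_protein_rate,
              intercept_meanlog = intercept_meanlog,
              intercept_sdlog = intercept_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_samples", "n_variants", "n_proteins", "ld_block_size",
              "n_chrom"))
    if (!is_count(cfg[[f]])) stop_config(f, "must be a positive integer")
  mr <- cfg$maf_range
  if (length(mr) != 2 || any(mr <= 0) || any(mr > 0.5) || mr[1] > mr[2])
    stop_config("maf_range", "must be two frequencies in (0, 0.5], low <= high")
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    stop_config("ld_decay", "must lie in [0, 1)")
  assert_prob(cfg$shared_peptide_fraction, "shared_peptide_fraction")
  assert_prob(cfg$missing_protein_rate, "missing_protein_rate", hi = 0.1)
  if (cfg$noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  pe <- cfg$planted_effects
  req <- c("variant", "protein", "beta", "class")
  if (!all(req %in% names(pe)))
    stop_config("planted_effects", "needs columns variant, protein, beta, class")
  if (nrow(pe)) {
    if (any(pe$variant < 1 | pe$variant > cfg$n_variants))
      stop_config("planted_effects", "variant index out of range")
    if (any(pe$protein < 1 | pe$protein > cfg$n_proteins))
      stop_config("planted_effects", "protein index out of range")
    if (!all(pe$class %in% c("local", "distant")))
      stop_config("planted_effects", "class must be 'local' or 'distant'")
  }
  invisible(cfg)
}

#' Simulate genotypes under a blocked Gaussian-copula LD model
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with dosages in \{0,1,2\} (complete; the
#'   simulator emulates a post-imputation call set).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  rho <- config$ld_decay
  mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(mafs)
  dosage <- matrix(0L, n, m)
  blocks <- split(seq_len(m),
                  ceiling(seq_len(m) / config$ld_block_size))
  for (idx in blocks) {
    B <- length(idx)
    for (copy in 1:2) {           # two haplotypes per sample
      z <- matrix(rnorm(n * B), n, B)
      if (rho > 0 && B > 1)
        for (j in 2:B) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      dosage[, idx] <- dosage[, idx] + (z < rep(thr[idx], each = n))
    }
  }
  # spread blocks contiguously over chromosomes; positions with 5-20 kb gaps
  chrom_of_block <- sort(rep_len(seq_len(config$n_chrom), length(blocks)))
  chrom <- chrom_of_block[ceiling(seq_len(m) / config$ld_block_size)]
  pos <- integer(m)
  for (c_ in unique(chrom)) {
    i <- which(chrom == c_)
    pos[i] <- 10000L + cumsum(as.integer(runif(length(i), 5000, 20000)))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  variants <- data.table(chrom = paste0("chr", chrom), pos = pos,
                         rsid = sprintf("rs%07d", seq_len(m)),
                         ref = ref, alt = alt, true_maf = mafs)
  genotype_matrix(dosage, variants,
                  samples = sprintf("L%03d", seq_len(n)))
}

#' Simulate the proteome on top of simulated genotypes
#'
#' Protein level = log-normal baseline + sum of planted additive dosage
#' effects + gender/ethnicity mean shifts + Gaussian noise, floored at a
#' small positive concentration (0.001 pmol/mg; with default baselines the
#' floor is essentially never hit). Correlated protein clusters arise when
#' several proteins share a planted variant. Gene coordinates are placed
#' within 1 Mb of the variant for `"local"` planted effects and on another
#' chromosome for `"distant"` ones.
#'
#' @param config a [sim_config()].
#' @param gm the matching [simulate_genotypes()] output.
#' @return list with `proteins` (a `protein_matrix` with injected
#'   missingness), `covariates` (sample, gender, ethnicity), and `truth`
#'   (planted betas, complete concentration matrix, cluster memberships).
#' @export
simulate_proteome <- function(config, gm) {
  validate_sim_config(config)
  if (ncol(gm$dosage) != config$n_variants ||
      nrow(gm$dosage) != config$n_samples)
    stop_config("planted_effects",
                "genotype matrix does not match the configuration")
  set.seed(config$seed + 1L)
  n <- config$n_samples
  np <- config$n_proteins
  pe <- as.data.table(config$planted_effects)

  covariates <- data.table(
    sample = gm$samples,
    gender = sample(c("F", "M"), n, replace = TRUE),
    ethnicity = sample(c("EUR", "AFR", "EAS"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1)))

  intercept <- rlnorm(np, config$intercept_meanlog, config$intercept_sdlog)
  g_eff <- rnorm(np, 0, config$gender_effect_sd)
  e_eff <- matrix(rnorm(np * 2, 0, config$ethnicity_effect_sd), np, 2,
                  dimnames = list(NULL, c("AFR", "EAS")))

  y <- matrix(rep(intercept, each = n), n, np)
  y <- y + outer(covariates$gender == "M", g_eff)
  for (lev in colnames(e_eff))
    y <- y + outer(covariates$ethnicity == lev, e_eff[, lev])
  for (k in seq_len(nrow(pe)))
    y[, pe$protein[k]] <- y[, pe$protein[k]] +
      pe$beta[k] * gm$dosage[, pe$variant[k]]
  if (config$noise_sd > 0)
    y <- y + matrix(rnorm(n * np, 0, config$noise_sd), n, np)
  conc_true <- t(pmax(y, 0.001))           # proteins x samples, pmol/mg

  ids <- sprintf("P%05d", seq_len(np))
  rownames(conc_true) <- ids
  colnames(conc_true) <- gm$samples

  meta <- simulate_protein_meta(config, gm, ids, pe)

  conc <- conc_true
  if (config$missing_protein_rate > 0) {
    # MCAR positions but a fixed per-protein count, capped so that every
    # protein keeps a strictly > 90% quantifiable fraction (binomial noise
    # around a raw rate could otherwise push single proteins below the rule)
    m_max <- n - floor(0.9 * n) - 1L
    m_miss <- min(floor(config$missing_protein_rate * n), max(m_max, 0L))
    if (m_miss > 0)
      for (i in seq_len(np))
        conc[i, sample.int(n, m_miss)] <- NA_real_
  }
  proteins <- structure(list(conc = conc, meta = meta, log = data.table()),
                        class = "protein_matrix")
  clusters <- if (nrow(pe))
    lapply(split(pe$protein, pe$variant), function(p) ids[sort(unique(p))])
  else list()
  list(proteins = proteins, covariates = covariates,
       truth = list(planted = pe, conc = conc_true, clusters = clusters,
                    intercept = intercept))
}

# gene coordinates honouring planted local/distant classes
simulate_protein_meta <- function(config, gm, ids, pe) {
  np <- length(ids)
  v <- gm$variants
  chrom_pool <- unique(v$chrom)
  chrom <- sample(chrom_pool, np, replace = TRUE)
  chr_max <- v[, max(pos), by = chrom]
  maxpos <- setNames(chr_max$V1, chr_max$chrom)
  start <- vapply(chrom, function(c_)
    as.integer(runif(1, 10000, maxpos[c_] + 5e5)), integer(1))
  len <- as.integer(runif(np, 5000, 100000))
  for (k in seq_len(nrow(pe))) {
    pi_ <- pe$protein[k]
    vp <- v$pos[pe$variant[k]]
    vc <- v$chrom[pe$variant[k]]
    if (pe$class[k] == "local") {
      chrom[pi_] <- vc
      start[pi_] <- max(10000L, vp + as.integer(runif(1, -5e5, 5e5)))
    } else {
      others <- setdiff(chrom_pool, vc)
      if (length(others)) chrom[pi_] <- sample(others, 1)
      else start[pi_] <- vp + 2e6 + as.integer(runif(1, 0, 5e5))
    }
  }
  protein_meta(data.table(
    protein = ids, gene = sub("^P", "G", ids), chrom = chrom,
    start = start, end = start + len,
    mass = rlnorm(np, log(5e4), 0.3)))
}

#' Simulate a peptide-level MS2 table from true concentrations
#'
#' Inverse of the TPA equations: each protein's per-sample target signal is
#' `concentration x mass x scale(sample)`, split over 2-4 peptides; a
#' `shared_peptide_fraction` of proteins carry one peptide shared with a
#' random partner, with the shared area equal to a fraction of the partners'
#' combined targets and the unique areas shrunk to compensate, so that
#' proportional redistribution recovers the targets exactly. A background
#' filler protein (`BGFILL01`, excluded from the truth) absorbs the remaining
#' signal so that the per-sample TPA denominator corresponds to exactly 1 mg
#' total protein, making the round trip exact rather than approximate.
#'
#' @param sim output of [simulate_proteome()].
#' @param config the same [sim_config()].
#' @return list with `table` (a [peptide_signal_table()]), `meta` (protein
#'   metadata including the background protein) and `shared_pairs`.
#' @export
simulate_peptides <- function(sim, config) {
  set.seed(config$seed + 2L)
  conc <- sim$proteins$conc                  # NA = missing in that sample
  meta <- sim$proteins$meta
  ids <- rownames(conc)
  np <- length(ids)
  samples <- colnames(conc)
  mass <- setNames(meta$mass, meta$protein)[ids]

  target <- conc * mass                      # per-protein signal, NA if absent
  target[is.na(target)] <- 0
  scale_s <- rlnorm(length(samples), log(1), 0.2)   # instrument scale/sample
  bg_mass <- 6e4
  bg_target <- pmax(1e9 - colSums(target), 0)
  if (any(bg_target == 0))
    stop("simulated proteome exceeds 1 mg of total protein; lower abundances")

  n_share <- floor(config$shared_peptide_fraction * np / 2) * 2
  sharers <- if (n_share >= 2) sample(np, n_share) else integer(0)
  pair_of <- rep(NA_integer_, np)
  if (length(sharers)) {
    a <- sharers[seq(1, n_share, 2)]
    b <- sharers[seq(2, n_share, 2)]
    pair_of[a] <- b
    pair_of[b] <- a
  }
  shared_frac <- runif(np, 0.2, 0.4)

  rows <- vector("list", np + 1L)
  pepid <- 0L
  new_pep <- function(group, areas) {
    pepid <<- pepid + 1L
    areas[areas <= 0] <- NA_real_
    c(list(peptide_id = sprintf("pep%06d", pepid),
           sequence = random_peptide_seq(), protein_ids = group),
      as.list(setNames(areas, samples)))
  }
  for (i in seq_len(np)) {
    tot <- target[i, ] * scale_s
    f <- if (!is.na(pair_of[i])) shared_frac[min(i, pair_of[i])] else 0
    uni <- (1 - f) * tot
    n_pep <- sample(2:4, 1)
    w <- runif(n_pep, 0.5, 1.5); w <- w / sum(w)
    pep <- lapply(seq_len(n_pep), function(k) new_pep(ids[i], uni * w[k]))
    if (!is.na(pair_of[i]) && i < pair_of[i]) {
      j <- pair_of[i]
      shared_area <- f * (target[i, ] + target[j, ]) * scale_s
      pep <- c(pep, list(new_pep(paste(ids[i], ids[j], sep = ";"),
                                 shared_area)))
    }
    rows[[i]] <- pep
  }
  # background filler peptides
  bw <- runif(5, 0.5, 1.5); bw <- bw / sum(bw)
  rows[[np + 1L]] <- lapply(seq_len(5), function(k)
    new_pep("BGFILL01", bg_target * scale_s * bw[k]))

  table <- peptide_signal_table(
    rbindlist(unlist(rows, recursive = FALSE)))
  meta_full <- protein_meta(rbind(
    as.data.table(meta),
    data.table(protein = "BGFILL01", gene = "BGFILL01", chrom = "chr1",
               start = 1L, end = 2L, mass = bg_mass)))
  pairs <- if (length(sharers))
    data.table(protein_a = ids[sharers[seq(1, n_share, 2)]],
               protein_b = ids[sharers[seq(2, n_share, 2)]])
  else data.table(protein_a = character(), protein_b = character())
  list(table = table, meta = meta_full, shared_pairs = pairs)
}

random_peptide_seq <- function(len = sample(8:20, 1)) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

#' Simulate annotations, trait catalog and an external QTL table
#'
#' Regulatory intervals per feature class, gene models with UTR/CDS/exon
#' structure derived from the protein metadata (plus a few non-coding RNA
#' genes), a variant-trait catalog keyed by simulated rsIDs, and an external
#' QTL summary table reusing this study's variants and proteins.
#'
#' @param config a [sim_config()].
#' @param gm simulated genotypes.
#' @param meta protein metadata (gene coordinates).
#' @param n_regulatory intervals per regulatory class (default 30).
#' @param n_trait_assoc catalog rows (default 50).
#' @param n_external_qtl external QTL rows (default 40).
#' @return list(regulatory, gene_models, traits, external_qtl).
#' @export
simulate_annotations <- function(config, gm, meta, n_regulatory = 30,
                                 n_trait_assoc = 50, n_external_qtl = 40) {
  set.seed(config$seed + 3L)
  v <- gm$variants
  chrom_pool <- unique(v$chrom)
  chr_max <- setNames(v[, max(pos), by = chrom]$V1, chrom_pool)

  regulatory <- rbindlist(lapply(REGULATORY_CLASSES, function(cl) {
    chrom <- sample(chrom_pool, n_regulatory, replace = TRUE)
    start <- vapply(chrom, function(c_)
      as.integer(runif(1, 1000, chr_max[c_])), integer(1))
    data.table(chrom = chrom, start = start,
               end = start + as.integer(runif(n_regulatory, 200, 2000)),
               class = cl)
  }))

  gene_models <- build_gene_models(meta, chrom_pool, chr_max)

  trait_pool <- c("alcohol dependence", "LDL cholesterol", "liver enzyme ALT",
                  "drug-induced liver injury", "bilirubin level",
                  "warfarin dose response", "nonalcoholic fatty liver disease",
                  "gamma-glutamyl transferase", "statin response",
                  "total cholesterol")
  traits <- data.table(
    rsid = sample(v$rsid, n_trait_assoc, replace = TRUE),
    trait = sample(trait_pool, n_trait_assoc, replace = TRUE),
    source = sample(c("gwas_catalog", "clinvar", "pharmgkb"), n_trait_assoc,
                    replace = TRUE, prob = c(0.5, 0.35, 0.15)))
  traits <- unique(traits)

  external_qtl <- data.table(
    rsid = sample(v$rsid, n_external_qtl, replace = TRUE),
    trait = sample(meta$protein, n_external_qtl, replace = TRUE),
    p = 10^runif(n_external_qtl, -12, -4))
  external_qtl <- unique(external_qtl, by = c("rsid", "trait"))

  list(regulatory = regulatory, gene_models = gene_models,
       traits = traits, external_qtl = external_qtl)
}

# UTR/CDS/exon structure per gene: 2-4 exons, 100 bp UTRs at the gene ends,
# CDS = exon minus UTR; plus a handful of non-coding RNA genes (exons only)
build_gene_models <- function(meta, chrom_pool, chr_max) {
  rows <- list()
  for (k in seq_len(nrow(meta))) {
    g <- meta[k]
    len <- g$end - g$start + 1L
    n_ex <- sample(2:4, 1)
    bounds <- sort(sample(seq(200L, len - 200L, by = 50L),
                          2L * n_ex - 2L))
    es <- c(0L, bounds[seq(2, length(bounds), 2)]) + g$start
    ee <- c(bounds[seq(1, length(bounds), 2)], len - 1L) + g$start
    exons <- data.table(gene_id = g$gene, biotype = "protein_coding",
                        feature = "exon", chrom = g$chrom,
                        start = es, end = ee)
    utr5 <- data.table(gene_id = g$gene, biotype = "protein_coding",
                       feature = "UTR", chrom = g$chrom,
                       start = es[1], end = min(es[1] + 99L, ee[1]))
    utr3 <- data.table(gene_id = g$gene, biotype = "protein_coding",
                       feature = "UTR", chrom = g$chrom,
                       start = max(ee[n_ex] - 99L, es[n_ex]), end = ee[n_ex])
    cds <- copy(exons)[, feature := "CDS"]
    cds$start[1] <- utr5$end + 1L
    cds$end[n_ex] <- utr3$start - 1L
    cds <- cds[start <= end]
    rows[[k]] <- rbind(
      data.table(gene_id = g$gene, biotype = "protein_coding",
                 feature = "gene", chrom = g$chrom,
                 start = g$start, end = g$end),
      exons, utr5, utr3, cds)
  }
  # non-coding RNA genes (10% of the coding count, at least 2)
  n_nc <- max(2L, nrow(meta) %/% 10L)
  for (k in seq_len(n_nc)) {
    chrom <- sample(chrom_pool, 1)
    start <- as.integer(runif(1, 10000, chr_max[chrom]))
    end <- start + as.integer(runif(1, 500, 5000))
    rows[[nrow(meta) + k]] <- rbind(
      data.table(gene_id = sprintf("NC%04d", k), biotype = "lincRNA",
                 feature = "gene", chrom = chrom, start = start, end = end),
      data.table(gene_id = sprintf("NC%04d", k), biotype = "lincRNA",
                 feature = "exon", chrom = chrom, start = start, end = end))
  }
  all <- rbindlist(rows)
  list(genes = all[feature == "gene",
                   .(gene_id, biotype, chrom, start, end)],
       features = rbind(
         all[feature != "gene", .(gene_id, feature, chrom, start, end)],
         derive_introns(all)))
}

derive_introns <- function(all) {
  rbindlist(lapply(split(all, all$gene_id), function(gdt) {
    g <- gdt[feature == "gene"]
    ex <- gdt[feature == "exon"]
    span <- IRanges::IRanges(g$start, g$end)
    exu <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    intr <- IRanges::setdiff(span, exu)
    if (!length(intr)) return(NULL)
    data.table(gene_id = g$gene_id, feature = "intron", chrom = g$chrom,
               start = IRanges::start(intr), end = IRanges::end(intr))
  }))
}

#' Run the full generator
#'
#' @param config a [sim_config()].
#' @return list: genotypes, proteins, covariates, peptides (table + meta),
#'   annotations, truth.
#' @export
simulate_study <- function(config) {
  gm <- simulate_genotypes(config)
  prot <- simulate_proteome(config, gm)
  pep <- simulate_peptides(prot, config)
  ann <- simulate_annotations(config, gm, prot$proteins$meta)
  list(genotypes = gm, proteins = prot$proteins,
       covariates = prot$covariates, peptides = pep,
       annotations = ann, truth = prot$truth)
}
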