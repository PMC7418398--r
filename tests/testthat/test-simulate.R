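test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(missing_protein_rate = 0.2), "missing_protein_rate")
  expect_error(sim_config(n_variants = 10, planted_effects = data.frame(
    variant = 11, protein = 1, beta = 1, class = "local")), "planted_effects")
  expect_error(sim_config(planted_effects = data.frame(
    variant = 1, protein = 1, beta = 1, class = "sideways")), "planted_effects")
})

test_that("fixed seed gives bit-identical outputs, different seeds differ", {
  cfg <- sim_config(n_samples = 30, n_variants = 50, n_proteins = 10, seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$proteins$conc, b$proteins$conc)
  expect_identical(a$peptides$table, b$peptides$table)
  expect_identical(a$annotations, b$annotations)

  c_ <- simulate_genotypes(sim_config(n_samples = 30, n_variants = 50,
                                      n_proteins = 10, seed = 6))
  expect_false(identical(a$genotypes$dosage, c_$dosage))
})

test_that("written files are identical under a fixed seed", {
  cfg <- sim_config(n_samples = 15, n_variants = 30, n_proteins = 6, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_study(cfg), d1)
  p2 <- write_simulation(simulate_study(cfg), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file", f))
})

test_that("degenerate maf range pins every allele frequency at 0.5", {
  cfg <- sim_config(n_samples = 50, n_variants = 40, n_proteins = 2,
                    maf_range = c(0.5, 0.5), seed = 2)
  gm <- simulate_genotypes(cfg)
  expect_true(all(gm$variants$true_maf == 0.5))
})

test_that("ld_decay = 0 gives independence-scale within-block r2", {
  cfg <- sim_config(n_samples = 2000, n_variants = 40, n_proteins = 2,
                    ld_block_size = 10, ld_decay = 0, n_chrom = 1, seed = 4)
  gm <- simulate_genotypes(cfg)
  r2s <- c()
  for (b in 0:3) {
    idx <- b * 10 + 1:10
    prs <- utils::combn(idx, 2)
    r2s <- c(r2s, apply(prs, 2, function(pr)
      ld_r2(gm$dosage[, pr[1]], gm$dosage[, pr[2]])))
  }
  # E[r2] under independence is ~ 1/(n-1)
  expect_lt(mean(r2s), 5 / (2000 - 1))
  expect_gt(mean(r2s), 0)
})

test_that("positive ld_decay induces decaying within-block correlation", {
  cfg <- sim_config(n_samples = 500, n_variants = 20, n_proteins = 2,
                    ld_block_size = 20, ld_decay = 0.9, n_chrom = 1,
                    maf_range = c(0.3, 0.5), seed = 12)
  gm <- simulate_genotypes(cfg)
  r2_adj <- mean(sapply(1:19, function(j)
    ld_r2(gm$dosage[, j], gm$dosage[, j + 1])))
  r2_far <- mean(sapply(1:10, function(j)
    ld_r2(gm$dosage[, j], gm$dosage[, j + 10])))
  expect_gt(r2_adj, 0.4)
  expect_lt(r2_far, r2_adj / 2)
})

test_that("noiseless planted effect shifts dosage groups by exactly beta", {
  cfg <- sim_config(n_samples = 60, n_variants = 20, n_proteins = 3,
                    noise_sd = 0, gender_effect_sd = 0, ethnicity_effect_sd = 0,
                    planted_effects = data.frame(variant = 4, protein = 2,
                                                 beta = 1, class = "local"),
                    missing_protein_rate = 0, seed = 10)
  st <- simulate_study(cfg)
  y <- st$proteins$conc["P00002", ]
  g <- st$genotypes$dosage[, 4]
  for (d in 1:2) {
    if (!any(g == d) || !any(g == d - 1)) next
    expect_equal(mean(y[g == d]) - mean(y[g == d - 1]), 1, tolerance = 1e-12)
  }
  # untouched protein is constant
  expect_equal(var(st$proteins$conc["P00001", ]), 0, tolerance = 1e-20)
})

test_that("a shared strong variant induces correlated protein clusters", {
  good <- vapply(1:20, function(s) {
    cfg <- sim_config(n_samples = 287, n_variants = 10, n_proteins = 3,
                      noise_sd = 0.2, maf_range = c(0.2, 0.5),
                      planted_effects = data.frame(
                        variant = 2, protein = 1:3, beta = 2,
                        class = "distant"),
                      missing_protein_rate = 0, seed = 200 + s)
    st <- simulate_study(cfg)
    rho <- spearman_matrix(st$proteins)$rho
    all(rho[upper.tri(rho)] > 0.5)
  }, logical(1))
  expect_gte(mean(good), 0.95)
})

test_that("missingness rate honours the configuration", {
  cfg0 <- sim_config(n_samples = 80, n_variants = 20, n_proteins = 25,
                     missing_protein_rate = 0, seed = 14)
  st0 <- simulate_study(cfg0)
  expect_false(anyNA(st0$proteins$conc))

  cfg5 <- sim_config(n_samples = 80, n_variants = 20, n_proteins = 25,
                     missing_protein_rate = 0.05, seed = 14)
  st5 <- simulate_study(cfg5)
  expect_gt(mean(is.na(st5$proteins$conc)), 0.02)
  expect_lt(mean(is.na(st5$proteins$conc)), 0.08)
  # every protein still eligible under the > 90% rule with rate <= 0.1
  expect_length(eligible_proteins(st5$proteins),
                nrow(st5$proteins$conc))
})

test_that("planted local genes are within 1 Mb, distant genes beyond", {
  pe <- data.frame(variant = c(3, 9), protein = c(1, 2), beta = 1,
                   class = c("local", "distant"))
  cfg <- sim_config(n_samples = 20, n_variants = 20, n_proteins = 4,
                    planted_effects = pe, n_chrom = 4, seed = 33)
  st <- simulate_study(cfg)
  v <- st$genotypes$variants
  meta <- st$proteins$meta
  cls <- classify_local_distant(
    v$chrom[pe$variant], v$pos[pe$variant],
    meta$chrom[pe$protein], meta$start[pe$protein], meta$end[pe$protein])
  expect_equal(cls, c("local", "distant"))
})

test_that("annotation intervals are sane and exons nest inside genes", {
  cfg <- sim_config(n_samples = 10, n_variants = 40, n_proteins = 15,
                    seed = 21)
  st <- simulate_study(cfg)
  ann <- st$annotations
  expect_true(all(ann$regulatory$start <= ann$regulatory$end))
  gmdl <- ann$gene_models
  expect_true(all(gmdl$features$start <= gmdl$features$end))
  for (g in gmdl$genes$gene_id) {
    gi <- gmdl$genes[gene_id == g]
    f <- gmdl$features[gene_id == g]
    expect_true(all(f$start >= gi$start & f$end <= gi$end),
                info = paste("gene", g))
  }
  # trait catalog rsIDs come from the simulated variants
  expect_true(all(ann$traits$rsid %in% st$genotypes$variants$rsid))
  expect_true(all(ann$external_qtl$trait %in% st$proteins$meta$protein))
})

test_that("planted betas are recovered by the scan within tolerance", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(n_samples = 287, n_variants = 5, n_proteins = 1,
                      maf_range = c(0.3, 0.3), ld_decay = 0, noise_sd = 1,
                      planted_effects = data.frame(variant = 2, protein = 1,
                                                   beta = 1, class = "local"),
                      missing_protein_rate = 0, seed = 5000 + s)
    gm <- simulate_genotypes(cfg)
    pr <- simulate_proteome(cfg, gm)
    f <- fit_additive(gm$dosage[, 2], pr$proteins$conc["P00001", ])
    abs(f$beta - 1) <= 0.15
  }, logical(1))
  # theoretical coverage: se = 1/sqrt(287 * 2 * 0.3 * 0.7) = 0.091, so
  # P(|error| <= 0.15) = P(|Z| <= 1.65) ~ 0.90; assert the binomial 99%
  # band around that rate rather than an unattainable 95%
  expect_gte(mean(hits), 0.82)
})
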