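test_that("protein eligibility uses a strict > 90% quantifiability rule", {
  conc <- matrix(1, 3, 287, dimnames = list(c("A", "B", "C"), NULL))
  conc["A", 1:26] <- NA   # present 261/287 = 0.9094 -> kept
  conc["B", 1:29] <- NA   # present 258/287 = 0.8990 -> dropped
  pm <- make_pm(conc)
  expect_setequal(eligible_proteins(pm), c("A", "C"))
  expect_setequal(eligible_proteins(make_pm(matrix(
    1, 2, 10, dimnames = list(c("X", "Y"), NULL)))), c("X", "Y"))
})

test_that("fit_additive matches the closed-form OLS slope", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(1.0, 2.0, 3.0, 1.1, 2.1, 2.9)
  f <- fit_additive(g, y)
  expect_equal(f$beta, 0.95, tolerance = 1e-10)   # cov/var = 3.8/4
  expect_equal(f$n, 6)
  # against lm as an independent route
  lmfit <- summary(lm(y ~ g))$coefficients
  expect_equal(f$beta, lmfit["g", "Estimate"], tolerance = 1e-10)
  expect_equal(f$se, lmfit["g", "Std. Error"], tolerance = 1e-10)
  expect_equal(f$p, lmfit["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("fit_additive equals lm with covariates and handles degenerate input", {
  set.seed(2)
  n <- 80
  g <- rbinom(n, 2, 0.4)
  cv <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- 0.4 * g + 0.8 * cv[, 1] + rnorm(n)
  f <- fit_additive(g, y, cv)
  ref <- summary(lm(y ~ g + cv))$coefficients
  expect_equal(f$beta, ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(f$p, ref["g", "Pr(>|t|)"], tolerance = 1e-10)

  # covariate orthogonal to the rest of the design leaves beta unchanged
  # (Frisch-Waugh orthogonality)
  orth <- residuals(lm(rnorm(n) ~ g + cv))
  f2 <- fit_additive(g, y, cbind(cv, orth = orth))
  f1 <- fit_additive(g, y, cv)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)

  expect_null(fit_additive(rep(1, n), y))          # constant dosage
  expect_null(fit_additive(g[1:3], y[1:3], cv[1:3, ]))  # too few cases
})

test_that("significance_threshold reproduces the genome-wide cutoff", {
  expect_equal(significance_threshold(1671387), 2.99e-8)
  expect_equal(significance_threshold(1), 0.05)
  expect_equal(significance_threshold(1000), 5e-5)
  expect_error(significance_threshold(0), "n_snps")
})

test_that("local/distant classification is inclusive at exactly 1 Mb", {
  expect_equal(classify_local_distant("chr8", 120000, "chr8", 1e5, 1.5e5),
               "local")                                  # inside the gene
  expect_equal(classify_local_distant("chr1", 120000, "chr8", 1e5, 1.5e5),
               "distant")                                # other chromosome
  expect_equal(classify_local_distant("chr8", 1150000, "chr8", 1e5, 1.5e5),
               "local")                                  # exactly 1 Mb
  expect_equal(classify_local_distant("chr8", 1150001, "chr8", 1e5, 1.5e5),
               "distant")                                # 1 Mb + 1
})

test_that("scan recovers planted effects without false positives", {
  pe <- data.frame(variant = c(5, 60, 120, 180, 240),
                   protein = 1:5, beta = 1.5, class = "local")
  cfg <- sim_config(n_samples = 287, n_variants = 300, n_proteins = 10,
                    maf_range = c(0.2, 0.5), ld_decay = 0, noise_sd = 1,
                    planted_effects = pe, missing_protein_rate = 0, seed = 17)
  st <- simulate_study(cfg)
  scan <- pqtl_scan(st$genotypes, st$proteins, covariates = st$covariates,
                    threshold = 2.99e-8)
  hits <- scan$records[, paste(rsid, protein)]
  planted <- paste(st$genotypes$variants$rsid[pe$variant],
                   sprintf("P%05d", pe$protein))
  expect_true(all(planted %in% hits))
  expect_equal(sort(hits), sort(planted))  # nothing else at 2.99e-8
})

test_that("permuted protein matrix yields no hits at the study threshold", {
  cfg <- sim_config(n_samples = 150, n_variants = 200, n_proteins = 8,
                    ld_decay = 0, missing_protein_rate = 0, seed = 23)
  st <- simulate_study(cfg)
  pm <- st$proteins
  set.seed(1)
  pm$conc <- pm$conc[, sample(ncol(pm$conc))]
  colnames(pm$conc) <- st$genotypes$samples
  scan <- pqtl_scan(st$genotypes, pm, threshold = 2.99e-8)
  expect_equal(nrow(scan$records), 0)
})

test_that("planted beta scaled against MAF gives a negative beta-MAF correlation", {
  set.seed(31)
  cfg0 <- sim_config(n_samples = 200, n_variants = 100, n_proteins = 20,
                     maf_range = c(0.05, 0.5), ld_decay = 0,
                     missing_protein_rate = 0, seed = 41)
  gm <- simulate_genotypes(cfg0)
  mafs <- apply(gm$dosage, 2, maf)
  vs <- order(mafs)[round(seq(1, 100, length.out = 20))]
  pe <- data.frame(variant = vs, protein = 1:20,
                   beta = 3 * (0.55 - mafs[vs]), class = "local")
  cfg <- sim_config(n_samples = 200, n_variants = 100, n_proteins = 20,
                    maf_range = c(0.05, 0.5), ld_decay = 0, noise_sd = 0.5,
                    planted_effects = pe, missing_protein_rate = 0, seed = 41)
  st <- simulate_study(cfg)
  scan <- pqtl_scan(st$genotypes, st$proteins, covariates = st$covariates,
                    threshold = 1e-4)
  expect_lt(scan$summary$beta_maf_rho, 0)
})

test_that("sample mismatch across inputs is an error naming the samples", {
  cfg <- sim_config(n_samples = 20, n_variants = 30, n_proteins = 4, seed = 2)
  st <- simulate_study(cfg)
  pm <- st$proteins
  colnames(pm$conc)[1] <- "STRANGER"
  expect_error(pqtl_scan(st$genotypes, pm), "STRANGER")
})

test_that("vectorized scan equals per-pair fit_additive", {
  cfg <- sim_config(n_samples = 60, n_variants = 40, n_proteins = 5,
                    planted_effects = data.frame(variant = 3, protein = 1,
                                                 beta = 1, class = "local"),
                    missing_protein_rate = 0.05, seed = 19)
  st <- simulate_study(cfg)
  design <- covariate_design(st$covariates, NULL, st$genotypes$samples)
  scan <- pqtl_scan(st$genotypes, st$proteins, covariates = design,
                    threshold = 0.01)
  expect_gt(nrow(scan$records), 0)
  for (k in seq_len(min(nrow(scan$records), 20))) {
    r <- scan$records[k]
    y <- st$proteins$conc[r$protein, st$genotypes$samples]
    f <- fit_additive(st$genotypes$dosage[, r$rsid], y, design)
    expect_equal(r$beta, f$beta, tolerance = 1e-10)
    expect_equal(r$p, f$p, tolerance = 1e-10)
    expect_equal(r$n, f$n)
  }
  # classification is exhaustive and records unique
  expect_true(all(scan$records$class %in% c("local", "distant")))
  expect_equal(anyDuplicated(scan$records[, .(rsid, protein)]), 0)
})

test_that("null p-values are uniform (KS) and type-I error is calibrated", {
  cfg <- sim_config(n_samples = 150, n_variants = 250, n_proteins = 10,
                    ld_decay = 0, missing_protein_rate = 0, seed = 29)
  st <- simulate_study(cfg)   # no planted effects
  scan <- pqtl_scan(st$genotypes, st$proteins, covariates = st$covariates,
                    threshold = 1)
  p <- scan$records$p
  expect_gt(length(p), 2400)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  n <- scan$n_tests
  for (alpha in c(0.05, 0.01)) {
    x <- sum(p < alpha)
    half <- 2.576 * sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(x / n - alpha), half + 1e-12)
  }
})

test_that("permutation FDR is small for strong signal, near 1 for pure noise", {
  pe <- data.frame(variant = c(5, 25), protein = 1:2, beta = 2,
                   class = "local")
  cfg <- sim_config(n_samples = 120, n_variants = 50, n_proteins = 4,
                    ld_decay = 0, noise_sd = 0.5, planted_effects = pe,
                    missing_protein_rate = 0, seed = 61)
  st <- simulate_study(cfg)
  res <- permutation_fdr(st$genotypes, st$proteins,
                         covariates = st$covariates,
                         threshold = 1e-6, n_perm = 5, seed = 2)
  expect_gte(res$n_observed, 2)
  expect_lt(res$fdr, 0.5)
  expect_equal(res$n_perm, 5)
})
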