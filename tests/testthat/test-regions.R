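test_that("BED ingest converts to 1-based inclusive and checks vocabulary", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t399\t600\tpromoter", "chr2\t0\t100\tenhancer"), bed)
  reg <- read_regulatory_bed(bed)
  expect_equal(reg$start, c(400L, 1L))
  expect_equal(reg$end, c(600L, 100L))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tnonsense_class", bad)
  expect_error(read_regulatory_bed(bad), "nonsense_class")
})

test_that("variant-to-regulatory mapping is position-inclusive", {
  regions <- data.frame(chrom = "chr1", start = 400L, end = 600L,
                        class = "promoter")
  v <- function(pos) data.frame(rsid = paste0("rs", pos), chrom = "chr1",
                                pos = pos)
  expect_equal(nrow(map_to_regulatory(v(500), regions)$hits), 1)
  expect_equal(nrow(map_to_regulatory(v(600), regions)$hits), 1)  # end inclusive
  expect_equal(nrow(map_to_regulatory(v(400), regions)$hits), 1)  # start inclusive
  expect_equal(nrow(map_to_regulatory(v(601), regions)$hits), 0)
  off <- data.frame(rsid = "rsX", chrom = "chrZ", pos = 500)
  expect_equal(nrow(map_to_regulatory(off, regions)$hits), 0)
})

test_that("GTF round trip and feature labels match the stabbing oracle", {
  cfg <- sim_config(n_samples = 10, n_variants = 60, n_proteins = 12,
                    seed = 9)
  st <- simulate_study(cfg)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models_gtf(st$annotations$gene_models, gtf)
  models <- read_gene_models(gtf)
  expect_setequal(models$genes$gene_id, st$annotations$gene_models$genes$gene_id)

  variants <- st$genotypes$variants[, .(rsid, chrom, pos)]
  labels <- map_to_gene_features(variants, models)
  feat <- models$features
  want <- oracle_stab(variants, feat)
  want_lab <- unique(data.frame(rsid = want$rsid,
                                gene_id = feat$gene_id[want$row],
                                feature = feat$feature[want$row]))
  got_lab <- as.data.frame(labels[feature != "intergenic",
                                  .(rsid, gene_id, feature)])
  expect_equal(
    sort(paste(got_lab$rsid, got_lab$gene_id, got_lab$feature)),
    sort(paste(want_lab$rsid, want_lab$gene_id, want_lab$feature)))
  # intergenic = no gene overlap
  genes <- models$genes
  gw <- oracle_stab(variants, genes)
  inter <- labels[feature == "intergenic"]$rsid
  expect_setequal(inter, setdiff(variants$rsid, gw$rsid))
})

test_that("a variant can be exonic for one gene and intronic for another", {
  models <- list(
    genes = data.table::data.table(
      gene_id = c("g1", "g2"), biotype = "protein_coding",
      chrom = "chr1", start = c(100L, 150L), end = c(1000L, 2000L)),
    features = data.table::data.table(
      gene_id = c("g1", "g1", "g2", "g2"),
      feature = c("exon", "intron", "intron", "exon"),
      chrom = "chr1",
      start = c(100L, 501L, 150L, 1500L),
      end = c(500L, 1000L, 1499L, 2000L)))
  lab <- map_to_gene_features(
    data.frame(rsid = "rs1", chrom = "chr1", pos = 300L), models)
  expect_setequal(lab[lab$gene_id == "g1"]$feature, "exon")
  expect_setequal(lab[lab$gene_id == "g2"]$feature, "intron")
})

test_that("regulator enrichment equals the hypergeometric oracle", {
  # universe of 1000 variants; 20 live in the exons of one gene; a protein
  # has 10 pQTLs of which 8 are among those exon variants
  universe <- data.frame(rsid = sprintf("rs%04d", 1:1000), chrom = "chr1",
                         pos = seq(1000L, by = 1000L, length.out = 1000))
  exon_vars <- universe$pos[1:20]
  models <- list(
    genes = data.table::data.table(gene_id = "g1", biotype = "protein_coding",
                                   chrom = "chr1", start = 1L,
                                   end = max(exon_vars) + 10L),
    features = data.table::data.table(
      gene_id = "g1", feature = "exon", chrom = "chr1",
      start = exon_vars, end = exon_vars))
  pqtls <- c(universe$rsid[1:8], universe$rsid[900:901])
  res <- regulator_enrichment(pqtls, universe, models)
  row <- res[gene_id == "g1" & feature == "exon"]
  expect_equal(row$a, 8L)
  expect_equal(row$b, 2L)
  expect_equal(row$c, 12L)
  expect_equal(row$d, 978L)
  expect_equal(row$p, oracle_fisher_p(8, 2, 12, 978), tolerance = 1e-10)
  expect_gte(row$p_adj, row$p)             # Bonferroni never below raw
  expect_error(regulator_enrichment(pqtls, universe[0, ], models), "universe")
})

test_that("proportional pQTL placement yields no significant regulator", {
  set.seed(66)
  universe <- data.frame(rsid = sprintf("rs%04d", 1:400), chrom = "chr1",
                         pos = seq(500L, by = 500L, length.out = 400))
  models <- list(
    genes = data.table::data.table(gene_id = "g1", biotype = "protein_coding",
                                   chrom = "chr1", start = 1L, end = 210000L),
    features = data.table::data.table(
      gene_id = "g1", feature = "intron", chrom = "chr1",
      start = 1L, end = 210000L))
  # pQTLs drawn uniformly: in/out proportions match the feature coverage
  pqtls <- sample(universe$rsid, 40)
  res <- regulator_enrichment(pqtls, universe, models)
  expect_true(all(res$p > 0.05) || all(!res$significant))
})

test_that("enrichment of permuted labels is significant <= 5% of the time", {
  set.seed(77)
  universe <- data.frame(rsid = sprintf("rs%04d", 1:300), chrom = "chr1",
                         pos = seq(500L, by = 500L, length.out = 300))
  models <- list(
    genes = data.table::data.table(gene_id = "g1", biotype = "protein_coding",
                                   chrom = "chr1", start = 1L, end = 50000L),
    features = data.table::data.table(
      gene_id = "g1", feature = "exon", chrom = "chr1",
      start = 1L, end = 50000L))
  hits <- vapply(1:60, function(i) {
    pq <- sample(universe$rsid, 30)    # label permutation: no real signal
    res <- regulator_enrichment(pq, universe, models)
    nrow(res) > 0 && any(res$p < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.10)   # 5% nominal, allowance for MC noise at n=60
})

test_that("local/distant distribution applies the double-counting convention", {
  # one variant, two local associations: in the CDS of PA's gene and the
  # promoter region of PB's gene -> counted twice, once per assignment
  records <- data.frame(rsid = c("rs1", "rs1"), protein = c("PA", "PB"),
                        gene = c("gA", "gB"), class = c("local", "local"))
  labels <- data.frame(rsid = "rs1", gene_id = c("gA", "gB"),
                       feature = c("CDS", "promoter"))
  d <- local_distant_region_distribution(records, labels)
  expect_equal(sum(d$n), 2)
  expect_equal(d[d$feature == "CDS"]$n, 1)
  expect_equal(d[d$feature == "promoter"]$n, 1)

  # without gene information every label of the variant counts per association
  d2 <- local_distant_region_distribution(
    records[, c("rsid", "protein", "class")],
    labels[, c("rsid", "feature")])
  expect_equal(sum(d2$n), 4)

  one <- local_distant_region_distribution(
    data.frame(rsid = "rs2", protein = "PA", class = "distant"),
    data.frame(rsid = "rs2", feature = "intron"))
  expect_equal(one$n, 1)
  empty <- local_distant_region_distribution(
    data.frame(rsid = character(), protein = character(),
               class = character()), labels)
  expect_equal(nrow(empty), 0)
})
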