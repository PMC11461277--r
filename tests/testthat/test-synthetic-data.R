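test_that("design arithmetic matches the emulated sampling scheme", {
  cfg <- simulation_config(populations_per_mode = 2, replicates = 3,
                           n_genes = 10, n_sco = 5)
  d <- generate_design(cfg)
  for (sp in cfg$species) {
    gam <- d[d$species == sp & d$tissue == "gamete", ]
    # 2 sexual pops x 2 sexes x 3 + 2 amazon pops x 3 = 18 gamete samples
    expect_equal(nrow(gam), 18)
    expect_true(all(table(gam$population, gam$sex)[c("sex1", "sex2"), ] == 3))
    amz <- gam[gam$mode == "amazon", ]
    expect_true(all(amz$sex == "female"))
    gen <- d[d$species == sp & d$population == "genlib", ]
    expect_equal(sum(gen$generation == "gametophyte"), 6)
    expect_equal(sum(gen$generation == "sporophyte"), 3)
  }
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(replicates = 0), "replicates")
  expect_error(simulation_config(frac_female_biased = 1.2),
               "frac_female_biased")
  expect_error(simulation_config(frac_female_biased = 0.7,
                                 frac_male_biased = 0.6),
               "frac_female_biased \\+ frac_male_biased")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(n_genes = 10, n_sco = 20), "n_sco")
})

test_that("same config and seed give byte-identical bundles", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 9, n_genes = 40, n_sco = 15,
                      n_planted_amazon_missense = 2)
  m1 <- write_fixture_bundle(simulate_bundle(cfg), file.path(dir, "a"))
  m2 <- write_fixture_bundle(simulate_bundle(cfg), file.path(dir, "b"))
  expect_identical(m1$md5, m2$md5)
  # manifest checksum changes iff content changes
  cfg2 <- small_config(seed = 10, n_genes = 40, n_sco = 15,
                       n_planted_amazon_missense = 2)
  m3 <- write_fixture_bundle(simulate_bundle(cfg2), file.path(dir, "c"))
  expect_false(all(m3$md5 == m1$md5))
})

test_that("zero planted fractions give all-negative truth labels", {
  cfg <- simulation_config(n_genes = 50, n_sco = 20,
                           frac_female_biased = 0, frac_male_biased = 0,
                           frac_convergent = 0, frac_haploid_specific = 0,
                           seed = 2)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  expect_true(all(sc$truth$genes$bias_class_planted == "unbiased"))
  expect_false(any(sc$truth$genes$haploid_specific))
  expect_false(any(sc$truth$scos$convergent))
})

test_that("planted fold changes are recovered by group means at large n", {
  cfg <- simulation_config(populations_per_mode = 1, replicates = 50,
                           n_genes = 300, n_sco = 10,
                           frac_female_biased = 0.1, frac_male_biased = 0,
                           bias_log2fc = 2, nb_dispersion = 0.05, seed = 4)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  sp <- cfg$species[1]
  tr <- sc$truth$genes[sc$truth$genes$species == sp, ]
  fb <- tr$gene_id[tr$bias_class_planted == "female_biased"]
  gam <- d[d$species == sp & d$tissue == "gamete" & d$mode == "sexual", ]
  cm <- sc$counts[[sp]]
  sf <- size_factors(cm, gam$sample_id)
  norm <- sweep(cm$counts[, gam$sample_id], 2, sf, "/")
  f <- rowMeans(norm[fb, gam$sample_id[gam$sex == "female"]])
  m <- rowMeans(norm[fb, gam$sample_id[gam$sex == "male"]])
  # planted log2fc = 2 -> ratio ~ 4 within sampling error at n = 50
  expect_equal(median(f / m), 4, tolerance = 0.12)
})

test_that("zero dispersion collapses to Poisson variance", {
  cfg <- simulation_config(populations_per_mode = 1, replicates = 60,
                           n_genes = 200, n_sco = 10, nb_dispersion = 0,
                           frac_female_biased = 0, frac_male_biased = 0,
                           frac_convergent = 0, baseline_log_sd = 0.3,
                           seed = 6)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  sp <- cfg$species[1]
  gam <- d[d$species == sp & d$tissue == "gamete" & d$sex == "female" &
             d$mode == "sexual", ]
  m <- sc$counts[[sp]]$counts[, gam$sample_id]
  # condition on the drawn library sizes: after dividing by per-sample
  # totals, var(c/L)/mean(c/L) ~ 1/L, so rescaling by the mean total
  # recovers the Poisson variance/mean ratio of 1
  L <- colSums(m)
  r <- sweep(m, 2, L, "/")
  vm <- (apply(r, 1, var) / rowMeans(r)) * mean(L)
  expect_equal(mean(vm), 1, tolerance = 0.1)
})

test_that("haploid-specific genes are silent in sporophyte libraries", {
  cfg <- small_config(seed = 8, frac_haploid_specific = 0.2)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  sp <- cfg$species[1]
  tr <- sc$truth$genes[sc$truth$genes$species == sp, ]
  hap <- tr$gene_id[tr$haploid_specific]
  spo <- d$sample_id[d$species == sp & d$generation == "sporophyte"]
  expect_true(all(sc$counts[[sp]]$counts[hap, spo] == 0))
})

test_that("theta = 0 with no planted candidates gives empty variant tables", {
  cfg <- simulation_config(n_genes = 30, n_sco = 10, theta_sexual = 0,
                           theta_amazon = 0, n_planted_amazon_missense = 0,
                           seed = 3)
  d <- generate_design(cfg)
  ann <- simulate_annotation(cfg)
  sv <- simulate_variants(d, ann, cfg)
  expect_equal(n_sites(sv$variants[[1]]), 0)
  expect_equal(n_sites(sv$variants[[2]]), 0)
  expect_null(sv$truth)
})

test_that("sexual populations carry more synonymous diversity than Amazons", {
  # Monte-Carlo check of the generative model across several datasets
  pis <- replicate(8, {
    cfg <- simulation_config(n_genes = 30, n_sco = 10, theta_sexual = 0.01,
                             theta_amazon = 0.002,
                             n_planted_amazon_missense = 0,
                             seed = sample.int(1e6, 1))
    d <- generate_design(cfg)
    ann <- simulate_annotation(cfg)
    sv <- simulate_variants(d, ann, cfg)
    sp <- cfg$species[1]
    gam <- d[d$species == sp & d$tissue == "gamete", ]
    sx <- gam$sample_id[gam$population == "sex1"]
    az <- gam$sample_id[gam$population == "amz1"]
    vt <- sv$variants[[sp]]
    ds <- gene_diversity(filter_variants_diversity(vt, sx), ann[[sp]], sx)
    da <- gene_diversity(filter_variants_diversity(vt, az), ann[[sp]], az)
    c(mean(ds$pi_s), mean(da$pi_s))
  })
  expect_gt(mean(pis[1, ]), mean(pis[2, ]))
})

test_that("fixture files round-trip and truth is written but separate", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 12, n_genes = 40, n_sco = 15,
                      n_planted_amazon_missense = 2)
  b <- simulate_bundle(cfg)
  write_fixture_bundle(b, dir)
  sp <- cfg$species[1]
  expect_identical(read_counts(file.path(dir, paste0("counts_", sp, ".tsv")))$counts,
                   b$counts[[sp]]$counts)
  expect_identical(read_sample_sheet(file.path(dir, "samples.tsv")),
                   b$design)
  vt <- read_vcf(file.path(dir, paste0("variants_", sp, ".vcf")))
  expect_identical(vt$sites, b$variants[[sp]]$sites)
  expect_identical(unname(vt$gt), unname(b$variants[[sp]]$gt))
  ann <- read_annotation(file.path(dir, paste0("annotation_", sp, ".gff")),
                         file.path(dir, paste0("cds_", sp, ".fasta")))
  expect_equal(ann$cds[names(b$annotation[[sp]]$cds)],
               b$annotation[[sp]]$cds)
  expect_true(file.exists(file.path(dir, "truth_genes.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})
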