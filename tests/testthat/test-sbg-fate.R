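fate_fixture <- local({
  cfg <- small_config(seed = 303, n_genes = 150, frac_female_biased = 0.08,
                      frac_male_biased = 0.08)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  sp <- cfg$species[1]
  tpm <- compute_tpm(sc$counts[[sp]])
  lt <- log_tpm(tpm)
  bt <- suppressWarnings(call_sex_biased(sc$counts[[sp]], d, sp))
  list(cfg = cfg, d = d, sc = sc, sp = sp, lt = lt, bt = bt)
})

test_that("class shift test reduces to the exact Mann-Whitney enumeration", {
  # construct a 3-gene class with per-gene means [1,2,3] vs [4,5,6]
  d <- fate_fixture$d
  sp <- fate_fixture$sp
  gam <- d[d$species == sp & d$tissue == "gamete", ]
  fem <- gam$sample_id[gam$mode == "sexual" & gam$sex == "female"]
  amz <- gam$sample_id[gam$mode == "amazon"]
  lt <- matrix(0, 3, ncol(fate_fixture$lt),
               dimnames = dimnames(fate_fixture$lt[1:3, ]))
  rownames(lt) <- c("ga", "gb", "gc")
  lt[, fem] <- matrix(rep(c(1, 2, 3), length(fem)), 3)
  lt[, amz] <- matrix(rep(c(4, 5, 6), length(amz)), 3)
  bias <- data.frame(gene_id = c("ga", "gb", "gc"), log2fc = -2,
                     p_value = 0, p_adj = 0, bias_class = "female_biased")
  class(bias) <- c("bias_table", "data.frame")
  res <- class_shift_test(lt, bias, d, sp, classes = "female_biased")
  expect_equal(res$U, 9)               # all amazon values above female
  expect_equal(res$p_value, 0.1)       # exact two-sided: 2/C(6,3)
  expect_equal(res$median_female, 2)
  expect_equal(res$median_amazon, 5)
  # identical groups -> p = 1
  lt[, amz] <- lt[, rep(fem[1], length(amz))]
  lt[, amz] <- matrix(rep(c(1, 2, 3), length(amz)), 3)
  res2 <- class_shift_test(lt, bias, d, sp, classes = "female_biased")
  expect_equal(res2$p_value, 1)
})

test_that("empty classes are flagged, not tested", {
  bias <- fate_fixture$bt
  bias$bias_class <- "unbiased"
  res <- class_shift_test(fate_fixture$lt, bias, fate_fixture$d,
                          fate_fixture$sp)
  expect_true(all(res$empty[res$bias_class != "unbiased"]))
  expect_true(all(is.na(res$p_value[res$empty])))
})

test_that("similarity index is a per-sample Pearson r with the invariances", {
  f <- fate_fixture
  si <- similarity_index(f$lt, f$bt, f$d, f$sp)
  expect_true(all(si$pearson_r >= -1 & si$pearson_r <= 1, na.rm = TRUE))
  gam <- f$d[f$d$species == f$sp & f$d$tissue == "gamete", ]
  amz <- gam$sample_id[gam$mode == "amazon"]
  expect_equal(sort(unique(si$amazon_sample_id)), sort(amz))
  # an amazon profile equal to the reference gives r = 1
  fem <- gam$sample_id[gam$mode == "sexual" & gam$sex == "female"]
  genes <- bias_class_genes(f$bt, "unbiased")[1:10]
  lt2 <- f$lt
  ref <- rowMeans(lt2[genes, fem])
  lt2[genes, amz[1]] <- ref
  si2 <- similarity_index(lt2, f$bt, f$d, f$sp, classes = "unbiased")
  # restrict to the constructed genes via a trimmed bias table
  bias10 <- f$bt[f$bt$gene_id %in% genes, ]
  class(bias10) <- c("bias_table", "data.frame")
  si3 <- similarity_index(lt2, bias10, f$d, f$sp, classes = "unbiased")
  expect_equal(si3$pearson_r[si3$amazon_sample_id == amz[1]], 1)
  # anti-correlated profile gives r = -1
  lt2[genes, amz[1]] <- -ref
  si4 <- similarity_index(lt2, bias10, f$d, f$sp, classes = "unbiased")
  expect_equal(si4$pearson_r[si4$amazon_sample_id == amz[1]], -1)
  # affine invariance
  lt2[genes, amz[1]] <- 3 * ref + 2
  si5 <- similarity_index(lt2, bias10, f$d, f$sp, classes = "unbiased")
  expect_equal(si5$pearson_r[si5$amazon_sample_id == amz[1]], 1)
})

test_that("dependent-correlation comparison has the stated limits", {
  expect_equal(compare_dependent_correlations(0.6, 0.6, 30, 0.4)$z, 0)
  expect_equal(compare_dependent_correlations(0.6, 0.6, 30, 0.4)$p_value, 1)
  # r_cross = 0 reduces to the independent two-sample Fisher z
  r <- compare_dependent_correlations(0.7, 0.2, 25, 0)
  z_ind <- (atanh(0.7) - atanh(0.2)) / sqrt(2 / (25 - 3))
  expect_equal(r$z, z_ind, tolerance = 1e-10)
  # symmetry under swapping
  a <- compare_dependent_correlations(0.8, 0.3, 40, 0.5)
  b <- compare_dependent_correlations(0.3, 0.8, 40, 0.5)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_error(compare_dependent_correlations(1, 0.5, 20, 0), "magnitude 1")
  expect_error(compare_dependent_correlations(0.5, 0.2, 3, 0), "at least 4")
})

test_that("defeminization read-out: planted Amazon down-shift of FBGs", {
  cfg <- simulation_config(n_genes = 150, n_sco = 40,
                           frac_female_biased = 0.1, frac_male_biased = 0,
                           frac_convergent = 0, bias_log2fc = 2,
                           seed = 71)
  d <- generate_design(cfg)
  sc <- simulate_counts(d, cfg)
  sp <- cfg$species[1]
  tr <- sc$truth$genes[sc$truth$genes$species == sp, ]
  fb <- tr$gene_id[tr$bias_class_planted == "female_biased"]
  # push FBG expression down in Amazons directly (1 log2 unit)
  cm <- sc$counts[[sp]]
  gam <- d[d$species == sp & d$tissue == "gamete", ]
  amz <- gam$sample_id[gam$mode == "amazon"]
  cm$counts[fb, amz] <- matrix(
    rnbinom(length(fb) * length(amz),
            mu = pmax(1, cm$counts[fb, amz] / 2), size = 5),
    length(fb))
  lt <- log_tpm(compute_tpm(cm))
  bias <- data.frame(gene_id = tr$gene_id, log2fc = 0, p_value = 1,
                     p_adj = 1, bias_class = tr$bias_class_planted)
  class(bias) <- c("bias_table", "data.frame")
  res <- class_shift_test(lt, bias, d, sp)
  fbg <- res[res$bias_class == "female_biased", ]
  expect_lt(fbg$median_amazon, fbg$median_female)
  si <- similarity_index(lt, bias, d, sp)
  r_fbg <- mean(si$pearson_r[si$bias_class == "female_biased"], na.rm = TRUE)
  r_unb <- mean(si$pearson_r[si$bias_class == "unbiased"], na.rm = TRUE)
  expect_lt(r_fbg, r_unb)
})

test_that("the regression-to-the-mean control runs and is deterministic", {
  f <- fate_fixture
  r1 <- suppressWarnings(rtm_control(f$sc$counts[[f$sp]], f$lt, f$d, f$sp))
  r2 <- suppressWarnings(rtm_control(f$sc$counts[[f$sp]], f$lt, f$d, f$sp))
  expect_identical(r1, r2)
  if (!r1$empty) {
    expect_gt(r1$n_control_genes, 0)
    expect_true(r1$direction %in% c("higher_in_female", "higher_in_amazon"))
  }
})
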