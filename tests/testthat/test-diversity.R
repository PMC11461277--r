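test_that("NG86 site counts match exhaustive enumeration for sense codons", {
  for (cd in c("TTT", "GGG", "ATG", "TGG", "CTA", "AGA")) {
    o <- oracle_codon_sites(cd)
    got <- ng86_site_counts(cd)
    expect_equal(got$S, unname(o["S"]), info = cd)
    expect_equal(got$N, unname(o["N"]), info = cd)
  }
  # conservation over a random CDS (terminal stop skipped)
  set.seed(2)
  sense <- setdiff(names(oracle_code), names(oracle_code)[oracle_code == "*"])
  cds <- paste(c(sample(sense, 30, TRUE), "TAA"), collapse = "")
  sc <- ng86_site_counts(cds)
  expect_equal(sc$S + sc$N, 90, tolerance = 1e-9)
  expect_equal(sc$n_codons, 30)
})

test_that("effect classification follows codon substitution, strand-aware", {
  genes <- data.frame(gene_id = c("gp", "gm"), contig = c("c1", "c2"),
                      strand = c("+", "-"))
  # gp: CDS AAA TTT TAA on + strand at 11..19
  # gm: CDS AAA CCC TAA on - strand: genome = revcomp = TTA GGG TTT
  exons <- data.frame(gene_id = c("gp", "gm"), start = c(11, 11),
                      end = c(19, 19))
  ann <- gene_annotation(genes, exons,
                         c(gp = "AAATTTTAA", gm = "AAACCCTAA"))
  # third-position AAA -> AAG: synonymous (Lys)
  e1 <- classify_effect(list(contig = "c1", pos = 13, ref = "A", alt = "G"),
                        ann)
  expect_equal(as.character(e1), "synonymous")
  # first-position AAA -> GAA: nonsynonymous (Lys -> Glu)
  e2 <- classify_effect(list(contig = "c1", pos = 11, ref = "A", alt = "G"),
                        ann)
  expect_equal(as.character(e2), "nonsynonymous")
  # minus strand: genomic position 19 is CDS base 1 (A, genomic T).
  # genomic T->C means coding A->G: AAA->GAA nonsynonymous
  e3 <- classify_effect(list(contig = "c2", pos = 19, ref = "T", alt = "C"),
                        ann)
  expect_equal(as.character(e3), "nonsynonymous")
  # genomic position 17 is CDS base 3: coding A->G AAA->AAG synonymous
  e4 <- classify_effect(list(contig = "c2", pos = 17, ref = "T", alt = "C"),
                        ann)
  expect_equal(as.character(e4), "synonymous")
  expect_error(classify_effect(list(contig = "c1", pos = 5, ref = "A",
                                    alt = "G"), ann), "noncoding")
  expect_error(classify_effect(list(contig = "c1", pos = 12, ref = "C",
                                    alt = "G"), ann), "mismatch")
})

test_that("strand round-trip: re-encoding a gene flips nothing", {
  # the same biological gene annotated on + and on - strand
  genes <- data.frame(gene_id = c("fwd", "rev"), contig = c("f", "r"),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("fwd", "rev"), start = c(1, 1),
                      end = c(9, 9))
  cds <- "ATGGCGTAA"
  ann <- gene_annotation(genes, exons, c(fwd = cds, rev = cds))
  # coding change at CDS index 4 (G->A): on + strand genomic pos 4 G->A;
  # on - strand genomic pos 6, complement base C->T
  ef <- classify_effect(list(contig = "f", pos = 4, ref = "G", alt = "A"),
                        ann)
  er <- classify_effect(list(contig = "r", pos = 6, ref = "C", alt = "T"),
                        ann)
  expect_identical(as.character(ef), as.character(er))
})

test_that("site pi equals the pairwise-difference oracle", {
  expect_equal(site_pi(3, 6), 0.6)
  expect_equal(site_pi(3, 6), oracle_site_pi(3, 6))
  expect_equal(site_pi(0, 5), 0)
  expect_equal(site_pi(5, 5), 0)
  expect_equal(site_pi(2, 7), site_pi(5, 7))
  set.seed(8)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    k <- sample(0:n, 1)
    expect_equal(site_pi(k, n), oracle_site_pi(k, n), tolerance = 1e-12)
  }
  expect_error(site_pi(1, 1), "at least 2")
})

test_that("diversity filter applies the carrier/depth/quality thresholds", {
  sites <- data.frame(contig = "c", pos = 1:4, ref = "A", alt = "G",
                      qual = c(30, 30, 30, 19))
  gt <- matrix(c(1, 0, 0,   # one carrier -> drop
                 1, 1, 0,   # kept
                 1, 1, 0,   # depth 6 on a carrier -> one valid carrier
                 1, 1, 0),  # qual 19 -> drop
               4, 3, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  dp <- matrix(20, 4, 3, dimnames = dimnames(gt))
  dp[3, 2] <- 6
  vt <- variant_table(sites, gt, dp, ifelse(gt == 1, dp, 0))
  kept <- filter_variants_diversity(vt, c("s1", "s2", "s3"))
  expect_equal(kept$sites$pos, 2L)
  # boundary: depth exactly 7, qual exactly 20, 2 carriers -> kept
  dp2 <- matrix(7, 4, 3, dimnames = dimnames(gt))
  sites2 <- sites; sites2$qual <- 20
  vt2 <- variant_table(sites2, gt, dp2, ifelse(gt == 1, dp2, 0))
  kept2 <- filter_variants_diversity(vt2, c("s1", "s2", "s3"))
  expect_true(all(c(2L, 3L, 4L) %in% kept2$sites$pos))
  # empty input passes through
  empty <- filter_variants_diversity(vt2, "s1")
  expect_equal(n_sites(filter_variants_diversity(empty, "s1")), 0)
})

test_that("gene diversity matches the hand example and the brute force", {
  # one synonymous SNP with k=3 of n=6 in a known CDS
  set.seed(31)
  sense <- setdiff(names(oracle_code), names(oracle_code)[oracle_code == "*"])
  cds <- paste(c(sample(sense, 40, TRUE), "TAA"), collapse = "")
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+")
  exons <- data.frame(gene_id = "g", start = 1, end = nchar(cds))
  ann <- gene_annotation(genes, exons, c(g = cds))
  # find a synonymous third-position change
  pos <- NA
  for (i in seq_len(40)) {
    cd <- substr(cds, 3 * i - 2, 3 * i)
    for (b in setdiff(c("A", "C", "G", "T"), substr(cd, 3, 3))) {
      mut <- cd; substr(mut, 3, 3) <- b
      if (oracle_translate(mut) == oracle_translate(cd)) {
        pos <- c(3 * i, b); break
      }
    }
    if (!is.na(pos[1])) break
  }
  samples <- paste0("s", 1:6)
  gt <- matrix(c(1, 1, 1, 0, 0, 0), 1, dimnames = list(NULL, samples))
  dp <- matrix(20, 1, 6, dimnames = list(NULL, samples))
  vt <- variant_table(
    data.frame(contig = "c", pos = as.integer(pos[1]),
               ref = substr(cds, as.integer(pos[1]), as.integer(pos[1])),
               alt = pos[2], qual = 40),
    gt, dp, ifelse(gt == 1, dp, 0))
  d <- gene_diversity(vt, ann, samples)
  S <- ng86_site_counts(cds)$S
  expect_equal(d$pi_s, 0.6 / S, tolerance = 1e-12)
  expect_equal(d$pi_n, 0)
  expect_equal(d$pi_ratio, 0)  # pi_s > 0, so the ratio is defined (= 0)
})

test_that("no variants give zero diversity and an undefined ratio", {
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+")
  exons <- data.frame(gene_id = "g", start = 1, end = 9)
  ann <- gene_annotation(genes, exons, c(g = "ATGGCGTAA"))
  samples <- paste0("s", 1:4)
  empty <- matrix(integer(0), 0, 4, dimnames = list(NULL, samples))
  vt <- variant_table(data.frame(contig = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 qual = numeric(0)), empty, empty, empty)
  d <- gene_diversity(vt, ann, samples)
  expect_equal(d$pi_s, 0)
  expect_equal(d$pi_n, 0)
  expect_true(is.na(d$pi_ratio))
})

test_that("per-gene pi agrees with an average-pairwise-difference oracle", {
  set.seed(77)
  cfg <- simulation_config(n_genes = 12, n_sco = 4, theta_sexual = 0.02,
                           n_planted_amazon_missense = 0, seed = 55)
  d <- generate_design(cfg)
  ann <- simulate_annotation(cfg)
  sv <- simulate_variants(d, ann, cfg)
  sp <- cfg$species[1]
  gam <- d[d$species == sp & d$tissue == "gamete", ]
  grp <- gam$sample_id[gam$population == "sex1"]
  vt <- filter_variants_diversity(sv$variants[[sp]], grp,
                                  min_carriers = 1)
  div <- gene_diversity(vt, ann[[sp]], grp)
  # oracle: per gene, sum over its sites of mean pairwise differences
  a <- ann[[sp]]
  for (g in div$gene_id[div$n_snps > 0][1:5]) {
    contig <- a$genes$contig[a$genes$gene_id == g]
    idx <- which(vt$sites$contig == contig)
    pis <- 0; pin <- 0
    for (i in idx) {
      gts <- vt$gt[i, grp]
      k <- sum(gts == 1); n <- length(gts)
      if (k == 0 || k == n) next
      eff <- classify_effect(vt$sites[i, ], a)
      if (eff == "synonymous") pis <- pis + oracle_site_pi(k, n)
      else pin <- pin + oracle_site_pi(k, n)
    }
    sc <- ng86_site_counts(a$cds[[g]])
    row <- div[div$gene_id == g, ]
    expect_equal(row$pi_s, pis / sc$S, tolerance = 1e-10)
    expect_equal(row$pi_n, pin / sc$N, tolerance = 1e-10)
  }
})

test_that("adding a synonymous segregating site never decreases pi_s", {
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+")
  cds <- "AAATTTGGGCCCTAA"
  exons <- data.frame(gene_id = "g", start = 1, end = nchar(cds))
  ann <- gene_annotation(genes, exons, c(g = cds))
  samples <- paste0("s", 1:6)
  mk <- function(pos_v, ref_v, alt_v) {
    n <- length(pos_v)
    gt <- matrix(rep(c(1, 1, 0, 0, 0, 0), n), n, byrow = TRUE,
                 dimnames = list(NULL, samples))
    dp <- matrix(20, n, 6, dimnames = list(NULL, samples))
    variant_table(data.frame(contig = "c", pos = pos_v, ref = ref_v,
                             alt = alt_v, qual = 40),
                  gt, dp, ifelse(gt == 1, dp, 0))
  }
  d1 <- gene_diversity(mk(3, "A", "G"), ann, samples)      # AAA->AAG syn
  d2 <- gene_diversity(mk(c(3, 6), c("A", "T"), c("G", "C")), ann, samples)
  expect_gte(d2$pi_s, d1$pi_s)
})

test_that("haploid-specific rule: gametophyte quota and sporophyte silence", {
  design <- data.frame(
    sample_id = c(paste0("gam", 1:6), paste0("spo", 1:3)),
    species = "sp", population = "genlib",
    sex = c(rep(c("female", "male"), 3), rep(NA, 3)),
    mode = "sexual",
    generation = c(rep("gametophyte", 6), rep("sporophyte", 3)),
    tissue = "thallus", replicate = 1)
  tpm <- matrix(0, 3, 9, dimnames = list(c("in4", "spo1", "gam3"),
                                         design$sample_id))
  tpm["in4", paste0("gam", 1:4)] <- 1       # 4/6 above, spo silent -> in
  tpm["spo1", paste0("gam", 1:4)] <- 1
  tpm["spo1", "spo1"] <- 1                  # expressed in a sporophyte -> out
  tpm["gam3", paste0("gam", 1:3)] <- 1      # 3/6 below quota -> out
  got <- haploid_specific_genes(tpm, design)
  expect_identical(got, "in4")
  expect_error(haploid_specific_genes(tpm, design[1:6, ]), "sporophyte")
})

test_that("LMM likelihood matches a direct marginal-likelihood oracle", {
  set.seed(13)
  n_genes <- 50
  dat <- expand.grid(gene = paste0("g", seq_len(n_genes)),
                     mode = c("sexual", "amazon"))
  u <- rnorm(n_genes, 0, 0.5)
  dat$log_expr <- rnorm(nrow(dat))
  dat$value <- 1 + 0.8 * (dat$mode == "amazon") + 0.2 * dat$log_expr +
    u[as.integer(factor(dat$gene))] + rnorm(nrow(dat), 0, 0.3)
  fit <- lme4::lmer(value ~ mode + log_expr + (1 | gene), data = dat,
                    REML = FALSE)
  # oracle: evaluate the marginal Gaussian likelihood per gene block
  marg_ll <- function(beta, s_g, s_e) {
    X <- model.matrix(~ mode + log_expr, dat)
    r <- dat$value - X %*% beta
    ll <- 0
    for (g in levels(factor(dat$gene))) {
      idx <- which(dat$gene == g)
      V <- diag(s_e^2, length(idx)) + s_g^2
      ll <- ll + mvt_dnorm(r[idx], V)
    }
    ll
  }
  mvt_dnorm <- function(r, V) {
    L <- chol(V)
    -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(L))) +
              sum(backsolve(L, r, transpose = TRUE)^2))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll_oracle <- marg_ll(lme4::fixef(fit), sqrt(vc$vcov[1]), sqrt(vc$vcov[2]))
  expect_equal(ll_oracle, as.numeric(logLik(fit)), tolerance = 1e-6)
  # no perturbation improves the fitted optimum materially
  best <- ll_oracle
  set.seed(14)
  for (i in 1:40) {
    b <- lme4::fixef(fit) + rnorm(3, 0, 0.05)
    sg <- abs(sqrt(vc$vcov[1]) + rnorm(1, 0, 0.05))
    se <- abs(sqrt(vc$vcov[2]) + rnorm(1, 0, 0.05))
    best <- max(best, marg_ll(b, sg, se))
  }
  expect_lt(best - ll_oracle, 1e-3)
  # and the packaged test detects the planted mode effect
  res <- lmm_group_test(dat)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$estimate, lme4::fixef(fit)[[2]], tolerance = 1e-8)
})

test_that("zero group difference gives a calm mode estimate", {
  set.seed(15)
  dat <- expand.grid(gene = paste0("g", 1:40), mode = c("a", "b"))
  dat$value <- rnorm(nrow(dat))
  res <- lmm_group_test(dat)
  expect_gt(res$p_value, 0.01)
  expect_lt(abs(res$estimate), 0.5)
})

test_that("binomial LRT without covariate equals the 2x2 G-test", {
  dat <- data.frame(successes = c(rep(1, 80), rep(0, 20),
                                  rep(1, 50), rep(0, 50)),
                    totals = 1,
                    mode = rep(c("sexual", "amazon"), each = 100))
  res <- binomial_snp_models(dat)
  O <- matrix(c(80, 20, 50, 50), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  G <- 2 * sum(O * log(O / E))
  expect_equal(res$statistic, G, tolerance = 1e-8)
  # identical groups -> near-zero effect
  dat2 <- data.frame(successes = rep(c(1, 0), 50), totals = 1,
                     mode = rep(c("a", "b"), each = 50))
  res2 <- binomial_snp_models(dat2)
  expect_lt(abs(res2$estimate), 1e-6)
})

test_that("GHQ GLMM likelihood matches Monte-Carlo integration", {
  set.seed(16)
  n_genes <- 10
  dat <- expand.grid(gene = paste0("g", seq_len(n_genes)),
                     mode = c("sexual", "amazon"))
  u <- rnorm(n_genes, 0, 0.8)
  eta <- -0.3 + 0.9 * (dat$mode == "amazon") +
    u[as.integer(factor(dat$gene))]
  dat$totals <- 40L
  dat$successes <- rbinom(nrow(dat), dat$totals, plogis(eta))
  res <- binomial_snp_models(dat, random = TRUE, nAGQ = 25)
  fit <- lme4::glmer(cbind(successes, totals - successes) ~ mode +
                       (1 | gene), data = dat, family = binomial(),
                     nAGQ = 25)
  beta <- lme4::fixef(fit)
  sg <- sqrt(as.data.frame(lme4::VarCorr(fit))$vcov[1])
  X <- model.matrix(~ mode, dat)
  eta0 <- as.vector(X %*% beta)
  set.seed(17)
  z <- rnorm(2e5)
  ll_mc <- 0
  for (g in levels(factor(dat$gene))) {
    idx <- which(dat$gene == g)
    lik_z <- rep(1, length(z))
    for (i in idx) {
      p <- plogis(eta0[i] + sg * z)
      lik_z <- lik_z * dbinom(dat$successes[i], dat$totals[i], p)
    }
    ll_mc <- ll_mc + log(mean(lik_z))
  }
  # lme4 reports the binomial log-likelihood without the saturated-model
  # constant; add it back before comparing with the true marginal value
  sat <- sum(dbinom(dat$successes, dat$totals,
                    dat$successes / dat$totals, log = TRUE))
  expect_equal(res$loglik_full + sat, ll_mc, tolerance = 0.02)
  expect_equal(res$loglik_full, as.numeric(logLik(fit)), tolerance = 1e-6)
})

test_that("class comparison matches the exact enumeration example", {
  ratios <- setNames(c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5), paste0("g", 1:6))
  r <- compare_gene_classes(ratios, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$mean_a, 0.1)
  expect_equal(r$mean_b, 0.5)
  r2 <- compare_gene_classes(ratios, character(0), paste0("g", 4:6))
  expect_true(r2$empty)
})
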