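# Within-population piN/piS from haploid variant tables and CDS models:
# Nei-Gojobori style site counting, codon-substitution effect
# classification, unbiased per-site pi, the haploid-specific gene rule and
# the group-comparison models (binomial GLM/GLMM, Gaussian LMM).

# per-codon synonymous site fraction for all sense codons, computed once by
# enumerating the nine single-base changes (stop-creating changes count as
# nonsynonymous, so S + N = 3 per codon)
.ng86_codon_table <- function() {
  if (is.null(.codon_env$ng86)) {
    bases <- c("A", "C", "G", "T")
    sense <- .sense_codons()
    syn <- vapply(sense, function(cd) {
      aa <- .translate_codon(cd)
      n_syn <- 0L
      for (p in 1:3) {
        for (b in setdiff(bases, substr(cd, p, p))) {
          mut <- cd
          substr(mut, p, p) <- b
          aa2 <- .translate_codon(mut)
          if (aa2 != "*" && aa2 == aa) n_syn <- n_syn + 1L
        }
      }
      n_syn / 3
    }, numeric(1))
    .codon_env$ng86 <- syn
  }
  .codon_env$ng86
}

#' Synonymous and nonsynonymous site counts of a CDS (NG86 counting)
#'
#' Each codon contributes S = (number of synonymous single-base changes)/3
#' and N = 3 - S; changes that create a stop codon count as nonsynonymous.
#' A terminal stop codon, if present, is skipped, as are codons containing
#' ambiguous bases (counted in `n_skipped`).
#'
#' @param cds CDS string (in frame, coding strand).
#' @return List: `S`, `N` (gene totals, S + N = 3 x sense codons),
#'   `codon_S`, `codon_N` (per scored codon), `n_codons`, `n_skipped`.
#' @export
ng86_site_counts <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) .stopf("CDS length is not a multiple of 3")
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (length(cods) > 0 && !is.na(.codon_aa_table()[cods[length(cods)]]) &&
      .is_stop_codon(cods[length(cods)]))
    cods <- cods[-length(cods)]
  tab <- .ng86_codon_table()
  known <- cods %in% names(tab)
  sc <- tab[cods[known]]
  list(S = sum(sc), N = sum(3 - sc),
       codon_S = unname(sc), codon_N = unname(3 - sc),
       n_codons = sum(known), n_skipped = sum(!known))
}

# map a genomic position to (gene, CDS index); returns NULL if noncoding
.locate_in_cds <- function(annotation, contig, pos) {
  ex <- annotation$exons
  genes <- annotation$genes
  cand <- genes$gene_id[genes$contig == contig]
  for (g in cand) {
    e <- ex[ex$gene_id == g, , drop = FALSE]
    hit <- which(pos >= e$start & pos <= e$end)
    if (length(hit) == 0) next
    strand <- genes$strand[genes$gene_id == g]
    lens <- e$end - e$start + 1
    if (strand == "+") {
      before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0
      idx <- before + (pos - e$start[hit] + 1)
    } else {
      after <- if (hit < nrow(e)) sum(lens[(hit + 1):nrow(e)]) else 0
      idx <- after + (e$end[hit] - pos + 1)
    }
    return(list(gene_id = g, cds_idx = idx, strand = strand))
  }
  NULL
}

#' Classify a variant as synonymous or nonsynonymous
#'
#' Substitutes the alternate base into the reference codon (reverse
#' complementing on minus-strand genes) and compares the translations;
#' stop gain/loss counts as nonsynonymous.
#'
#' @param variant List or one-row data.frame with contig, pos, ref, alt.
#' @param annotation A [gene_annotation()].
#' @return "synonymous" or "nonsynonymous" with attribute `gene_id`.
#' @export
classify_effect <- function(variant, annotation) {
  loc <- .locate_in_cds(annotation, variant$contig, variant$pos)
  if (is.null(loc))
    .stopf("position %s:%d is not inside an exon (noncoding)",
           variant$contig, as.integer(variant$pos))
  cds <- annotation$cds[[loc$gene_id]]
  ref_c <- toupper(variant$ref); alt_c <- toupper(variant$alt)
  if (loc$strand == "-") {
    ref_c <- .complement(ref_c)
    alt_c <- .complement(alt_c)
  }
  codon_n <- (loc$cds_idx - 1) %/% 3 + 1
  pos_in <- (loc$cds_idx - 1) %% 3 + 1
  codon <- substr(cds, 3 * codon_n - 2, 3 * codon_n)
  if (substr(codon, pos_in, pos_in) != ref_c)
    .stopf("reference base mismatch at %s:%d (gene %s)",
           variant$contig, as.integer(variant$pos), loc$gene_id)
  mut <- codon
  substr(mut, pos_in, pos_in) <- alt_c
  eff <- if (.translate_codon(mut) == .translate_codon(codon))
    "synonymous" else "nonsynonymous"
  attr(eff, "gene_id") <- loc$gene_id
  eff
}

#' Filter variants for diversity estimation
#'
#' Keeps sites where, within the given sample group, at least
#' `min_carriers` samples carry the alternate allele with read depth at
#' least `min_dp`, and the site quality is at least `min_qual`
#' (thresholds inclusive). Calls below `min_dp` are treated as missing.
#'
#' @param vt A [variant_table()].
#' @param samples Sample ids of the group.
#' @param min_carriers Minimum alt carriers. Default 2.
#' @param min_dp Minimum per-call depth. Default 7.
#' @param min_qual Minimum site quality. Default 20.
#' @return Filtered [variant_table()] (possibly zero rows).
#' @export
filter_variants_diversity <- function(vt, samples, min_carriers = 2,
                                      min_dp = 7, min_qual = 20) {
  stopifnot(inherits(vt, "variant_table"))
  if (length(samples) == 0) .stopf("empty sample group")
  miss <- setdiff(samples, vt$samples)
  if (length(miss) > 0) .stopf("unknown sample id(s): %s", miss[1])
  if (n_sites(vt) == 0) return(vt)
  gt <- vt$gt[, samples, drop = FALSE]
  dp <- vt$dp[, samples, drop = FALSE]
  valid <- !is.na(gt) & dp >= min_dp
  carriers <- rowSums(gt == 1 & valid, na.rm = TRUE)
  keep <- carriers >= min_carriers & vt$sites$qual >= min_qual
  variant_table(vt$sites[keep, , drop = FALSE],
                vt$gt[keep, , drop = FALSE],
                vt$dp[keep, , drop = FALSE],
                vt$alt_reads[keep, , drop = FALSE])
}

#' Unbiased per-site nucleotide diversity among haploid samples
#'
#' `pi = n/(n-1) * 2 * (k/n) * (1 - k/n)`, the average pairwise difference
#' at the site among n called haploid samples of which k carry the
#' alternate allele.
#'
#' @param alt_count k, number of alt calls (0 <= k <= n).
#' @param called n, number of called samples (>= 2).
#' @return Numeric pi.
#' @export
site_pi <- function(alt_count, called) {
  if (any(called < 2)) .stopf("at least 2 called samples are required")
  if (any(alt_count < 0 | alt_count > called))
    .stopf("alt_count must lie in [0, called]")
  p <- alt_count / called
  (called / (called - 1)) * 2 * p * (1 - p)
}

#' Per-gene piN and piS for one sample group
#'
#' Variants (pre-filtered with [filter_variants_diversity()]) are assigned
#' to genes and classified; per-site pi values are summed over synonymous
#' and nonsynonymous sites and divided by the NG86 synonymous and
#' nonsynonymous site counts of the gene's CDS. The piN/piS ratio is
#' undefined (NA) when piS = 0.
#'
#' @param vt Filtered [variant_table()].
#' @param annotation A [gene_annotation()].
#' @param samples Sample ids of the group.
#' @param group Label recorded in the output. Default "group".
#' @param min_dp Depth below which a call counts as missing. Default 7.
#' @return `diversity_table` data.frame: gene_id, group, n_samples,
#'   syn_sites, nonsyn_sites, pi_s, pi_n, pi_ratio, n_snps,
#'   n_variable_sites, cds_len.
#' @export
gene_diversity <- function(vt, annotation, samples, group = "group",
                           min_dp = 7) {
  stopifnot(inherits(vt, "variant_table"),
            inherits(annotation, "gene_annotation"))
  genes <- annotation$genes$gene_id
  sums <- new.env(parent = emptyenv())
  for (g in genes) assign(g, c(pis = 0, pin = 0, nsnp = 0), envir = sums)
  if (n_sites(vt) > 0) {
    gt <- vt$gt[, samples, drop = FALSE]
    dp <- vt$dp[, samples, drop = FALSE]
    valid <- !is.na(gt) & dp >= min_dp
    k <- rowSums(gt == 1 & valid, na.rm = TRUE)
    n <- rowSums(valid)
    for (i in seq_len(n_sites(vt))) {
      if (n[i] < 2 || k[i] == 0 || k[i] == n[i]) next
      eff <- tryCatch(classify_effect(vt$sites[i, ], annotation),
                      error = function(e) NULL)
      if (is.null(eff)) next
      g <- attr(eff, "gene_id")
      cur <- get(g, envir = sums)
      pi <- site_pi(k[i], n[i])
      if (eff == "synonymous") cur["pis"] <- cur["pis"] + pi
      else cur["pin"] <- cur["pin"] + pi
      cur["nsnp"] <- cur["nsnp"] + 1
      assign(g, cur, envir = sums)
    }
  }
  rows <- lapply(genes, function(g) {
    sites <- ng86_site_counts(annotation$cds[[g]])
    cur <- get(g, envir = sums)
    pi_s <- cur[["pis"]] / sites$S
    pi_n <- cur[["pin"]] / sites$N
    data.frame(gene_id = g, group = group, n_samples = length(samples),
               syn_sites = sites$S, nonsyn_sites = sites$N,
               pi_s = pi_s, pi_n = pi_n,
               pi_ratio = if (pi_s > 0) pi_n / pi_s else NA_real_,
               n_snps = cur[["nsnp"]],
               n_variable_sites = cur[["nsnp"]],
               cds_len = 3 * sites$n_codons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Haploid-specific (gametophyte-specific) genes
#'
#' A gene is haploid specific when its TPM exceeds `threshold` in at least
#' `ceiling(quota_fraction * n_gametophyte)` gametophyte libraries and in
#' zero sporophyte libraries (default: at least four of six gametophyte
#' libraries, none of the sporophytes).
#'
#' @param tpm TPM matrix.
#' @param design Sample sheet rows for the generation libraries (must
#'   contain both generations).
#' @param threshold Expression threshold (strict). Default 0.4.
#' @param quota_fraction Gametophyte quota fraction. Default 4/6.
#' @return Character vector of gene ids.
#' @export
haploid_specific_genes <- function(tpm, design, threshold = 0.4,
                                   quota_fraction = 4 / 6) {
  validate_sample_sheet(design)
  gam <- design$sample_id[design$generation == "gametophyte"]
  spo <- design$sample_id[design$generation == "sporophyte"]
  if (length(gam) == 0 || length(spo) == 0)
    .stopf("design must contain both gametophyte and sporophyte libraries")
  quota <- ceiling(quota_fraction * length(gam))
  g_ok <- rowSums(tpm[, gam, drop = FALSE] > threshold) >= quota
  s_ok <- rowSums(tpm[, spo, drop = FALSE] > threshold) == 0
  rownames(tpm)[g_ok & s_ok]
}

#' Linear mixed model test for a reproductive-mode effect
#'
#' Gaussian LMM (fitted by ML) of a per-gene response (e.g. piS or
#' piN/piS) on reproductive mode plus a log-expression covariate, with a
#' gene random intercept; the mode effect is tested by a likelihood ratio
#' test against the mode-dropped model (chi-square, 1 df). Singular fits
#' (zero between-gene variance) fall back to an ordinary regression LRT.
#'
#' @param data data.frame with columns `value`, `mode`, `gene` and
#'   optionally `log_expr`.
#' @return List: `p_value`, `statistic`, `estimate` (mode coefficient),
#'   `singular_fallback`.
#' @export
lmm_group_test <- function(data) {
  .assert_cols(data, c("value", "mode", "gene"), "lmm data")
  data <- data[is.finite(data$value), , drop = FALSE]
  if (length(unique(data$mode)) < 2) .stopf("need at least 2 groups")
  has_cov <- "log_expr" %in% names(data)
  rhs <- if (has_cov) "mode + log_expr" else "mode"
  full <- suppressMessages(lme4::lmer(
    as.formula(paste("value ~", rhs, "+ (1 | gene)")),
    data = data, REML = FALSE))
  if (lme4::isSingular(full, tol = 1e-5)) {
    f_full <- stats::lm(as.formula(paste("value ~", rhs)), data = data)
    rhs_red <- if (has_cov) "log_expr" else "1"
    f_red <- stats::lm(as.formula(paste("value ~", rhs_red)), data = data)
    stat <- max(0, 2 * (as.numeric(logLik(f_full)) -
                          as.numeric(logLik(f_red))))
    return(list(p_value = pchisq(stat, 1, lower.tail = FALSE),
                statistic = stat,
                estimate = coef(f_full)[[2]], singular_fallback = TRUE))
  }
  red <- suppressMessages(lme4::lmer(
    as.formula(paste("value ~", if (has_cov) "log_expr" else "1",
                     "+ (1 | gene)")),
    data = data, REML = FALSE))
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  list(p_value = pchisq(stat, 1, lower.tail = FALSE), statistic = stat,
       estimate = lme4::fixef(full)[[2]], singular_fallback = FALSE)
}

#' Binomial models for SNP presence / variable-site fractions
#'
#' Logit-link binomial GLM of per-gene successes/totals (e.g. genes with
#' SNPs, or variable sites over CDS length) on reproductive mode plus an
#' optional log-expression covariate; the mode effect is a chi-square LRT.
#' With `random = TRUE` a gene random intercept is added and the model is
#' fitted by adaptive Gauss-Hermite quadrature (`nAGQ` points). Complete
#' separation triggers a continuity-corrected refit (+0.5 to both margins),
#' flagged in the result.
#'
#' @param data data.frame with columns `successes`, `totals`, `mode`,
#'   optionally `log_expr` and (for `random = TRUE`) `gene`.
#' @param random Add a gene random intercept (GLMM). Default FALSE.
#' @param nAGQ Quadrature points for the GLMM. Default 9.
#' @return List: `p_value`, `statistic`, `estimate`, `penalized`,
#'   `loglik_full`.
#' @export
binomial_snp_models <- function(data, random = FALSE, nAGQ = 9) {
  .assert_cols(data, c("successes", "totals", "mode"), "binomial data")
  has_cov <- "log_expr" %in% names(data)
  rhs <- if (has_cov) "mode + log_expr" else "mode"
  rhs_red <- if (has_cov) "log_expr" else "1"
  data$failures <- data$totals - data$successes
  penalized <- FALSE
  fit2 <- function(dat) {
    if (random) {
      .assert_cols(dat, "gene", "binomial GLMM data")
      full <- lme4::glmer(
        as.formula(paste("cbind(successes, failures) ~", rhs, "+ (1 | gene)")),
        data = dat, family = stats::binomial(), nAGQ = nAGQ)
      red <- lme4::glmer(
        as.formula(paste("cbind(successes, failures) ~", rhs_red,
                         "+ (1 | gene)")),
        data = dat, family = stats::binomial(), nAGQ = nAGQ)
      list(full = full, red = red, est = lme4::fixef(full)[[2]])
    } else {
      full <- stats::glm(
        as.formula(paste("cbind(successes, failures) ~", rhs)),
        data = dat, family = stats::binomial())
      red <- stats::glm(
        as.formula(paste("cbind(successes, failures) ~", rhs_red)),
        data = dat, family = stats::binomial())
      list(full = full, red = red, est = coef(full)[[2]])
    }
  }
  sep <- FALSE
  res <- withCallingHandlers(
    fit2(data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) {
    dat2 <- data
    dat2$successes <- dat2$successes + 0.5
    dat2$failures <- dat2$failures + 0.5
    res <- suppressWarnings(fit2(dat2))
    penalized <- TRUE
  }
  ll_f <- as.numeric(logLik(res$full))
  ll_r <- as.numeric(logLik(res$red))
  stat <- max(0, 2 * (ll_f - ll_r))
  list(p_value = pchisq(stat, 1, lower.tail = FALSE), statistic = stat,
       estimate = res$est, penalized = penalized, loglik_full = ll_f)
}

#' Compare piN/piS ratios between two gene classes
#'
#' Two-sided Mann-Whitney test with tie correction plus class means.
#'
#' @param ratios Named numeric vector of per-gene ratios (NA allowed).
#' @param class_a,class_b Character vectors of gene ids.
#' @return List: `mean_a`, `mean_b`, `n_a`, `n_b`, `U`, `p_value`,
#'   `empty` flag.
#' @export
compare_gene_classes <- function(ratios, class_a, class_b) {
  a <- ratios[intersect(class_a, names(ratios))]
  b <- ratios[intersect(class_b, names(ratios))]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    return(list(mean_a = NA_real_, mean_b = NA_real_, n_a = length(a),
                n_b = length(b), U = NA_real_, p_value = NA_real_,
                empty = TRUE))
  wt <- .mw_test(a, b)
  list(mean_a = mean(a), mean_b = mean(b), n_a = length(a),
       n_b = length(b), U = wt$U, p_value = wt$p, empty = FALSE)
}
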