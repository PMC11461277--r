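# Two-sample Mann-Whitney with an exact null when feasible: untied small
# samples use the exact distribution; tied small samples are enumerated
# completely; otherwise the tie-corrected normal approximation is used.
.mw_exact_p <- function(a, b) {
  vals <- c(a, b)
  na <- length(a)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(length(vals), na)
  Us <- apply(combs, 2, function(ix) {
    sum(outer(vals[ix], vals[-ix], ">")) +
      0.5 * sum(outer(vals[ix], vals[-ix], "=="))
  })
  min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
}

.mw_test <- function(a, b) {
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  ties <- anyDuplicated(c(a, b)) > 0
  small <- length(a) <= 20 && length(b) <= 20
  p <- if (!ties && small) {
    suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  } else if (ties && choose(length(a) + length(b), length(a)) <= 20000) {
    .mw_exact_p(a, b)
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                 correct = TRUE)$p.value)
  }
  list(U = U, p = p)
}

# Fate of sex-biased genes after the switch to asexuality:
# class-wise expression-shift tests (defeminization / masculinization),
# the Pearson similarity index between Amazon samples and the sexual-female
# reference profile, a dependent-correlation comparison, and the
# regression-to-the-mean control.

.sbg_samples <- function(design, species) {
  validate_sample_sheet(design)
  sub <- design[design$species == species &
                  design$generation == "gametophyte", , drop = FALSE]
  if ("tissue" %in% names(sub))
    sub <- sub[sub$tissue == "gamete", , drop = FALSE]
  list(female = sub$sample_id[sub$mode == "sexual" & sub$sex == "female"],
       male = sub$sample_id[sub$mode == "sexual" & sub$sex == "male"],
       amazon = sub$sample_id[sub$mode == "amazon"])
}

#' Class-wise expression shift between sexual females and Amazons
#'
#' For each bias class, per-gene mean log2(TPM+1) profiles are computed in
#' sexual females and in Amazons and the two vectors are compared across
#' genes with a two-sided Mann-Whitney test (exact null when both classes
#' have at most 20 genes and there are no ties).
#'
#' @param logtpm log2(TPM+1) matrix.
#' @param bias_table A `bias_table` from [call_sex_biased()].
#' @param design Sample sheet.
#' @param species Species to analyse.
#' @param classes Bias classes to report. Default all three.
#' @return data.frame: species, bias_class, n_genes, median log2(TPM+1) in
#'   females and Amazons, U statistic, two-sided p (NA with a flag when the
#'   class is empty).
#' @export
class_shift_test <- function(logtpm, bias_table, design, species,
                             classes = c("female_biased", "male_biased",
                                         "unbiased")) {
  grp <- .sbg_samples(design, species)
  if (length(grp$female) == 0 || length(grp$amazon) == 0)
    .stopf("species %s needs sexual-female and amazon samples", species)
  out <- lapply(classes, function(cl) {
    genes <- intersect(bias_class_genes(bias_table, cl), rownames(logtpm))
    if (length(genes) == 0)
      return(data.frame(species = species, bias_class = cl, n_genes = 0L,
                        median_female = NA_real_, median_amazon = NA_real_,
                        U = NA_real_, p_value = NA_real_, empty = TRUE))
    x <- rowMeans(logtpm[genes, grp$female, drop = FALSE])
    y <- rowMeans(logtpm[genes, grp$amazon, drop = FALSE])
    wt <- .mw_test(y, x)
    data.frame(species = species, bias_class = cl,
               n_genes = length(genes),
               median_female = median(x), median_amazon = median(y),
               U = wt$U, p_value = wt$p,
               empty = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson similarity index between Amazon samples and the female reference
#'
#' The reference profile is the per-gene mean of log2(TPM+1) over all
#' sexual-female samples of the species; for each Amazon sample and each
#' bias class the Pearson correlation between reference and sample profile
#' is reported.
#'
#' @inheritParams class_shift_test
#' @return data.frame: species, amazon_sample_id, bias_class, pearson_r,
#'   n_genes, zero_variance flag (r is NA when either profile is constant).
#' @export
similarity_index <- function(logtpm, bias_table, design, species,
                             classes = c("female_biased", "male_biased",
                                         "unbiased")) {
  grp <- .sbg_samples(design, species)
  if (length(grp$female) == 0 || length(grp$amazon) == 0)
    .stopf("species %s needs sexual-female and amazon samples", species)
  rows <- list()
  for (cl in classes) {
    genes <- intersect(bias_class_genes(bias_table, cl), rownames(logtpm))
    if (length(genes) < 3) next
    ref <- rowMeans(logtpm[genes, grp$female, drop = FALSE])
    for (s in grp$amazon) {
      prof <- logtpm[genes, s]
      flat <- sd(ref) == 0 || sd(prof) == 0
      rows[[length(rows) + 1]] <- data.frame(
        species = species, amazon_sample_id = s, bias_class = cl,
        pearson_r = if (flat) NA_real_ else cor(ref, prof),
        n_genes = length(genes), zero_variance = flat)
    }
  }
  do.call(rbind, rows)
}

#' Compare two dependent, non-overlapping correlations
#'
#' Fisher-z comparison of two correlations measured on the same n samples
#' over disjoint gene sets, using the backtransformed-average correlation
#' (Silver-Hittner) in the covariance term. The dependency between the two
#' estimates enters through a single exchangeable cross-correlation
#' `r_cross` between the two gene-set profiles, giving
#' `cov = 2 r_cross^2 / (1 + rbar)^2`; at `r_cross = 0` the statistic
#' reduces exactly to the independent two-sample Fisher-z test. A Zou-style
#' confidence interval for `r1 - r2` is reported alongside.
#'
#' @param r1,r2 The two correlations, each in (-1, 1).
#' @param n Number of samples both correlations were computed on (>= 4).
#' @param r_cross Cross-correlation between the two profiles.
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return List: `z`, `p_value` (two-sided normal), `ci_lower`, `ci_upper`.
#' @export
compare_dependent_correlations <- function(r1, r2, n, r_cross,
                                           conf_level = 0.95) {
  if (n < 4) .stopf("n must be at least 4")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    .stopf("correlations of magnitude 1 give an infinite z")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- tanh((z1 + z2) / 2)
  cv <- 2 * r_cross^2 / (1 + rbar)^2
  cv <- min(cv, 0.999)
  z <- (z1 - z2) / sqrt((2 - 2 * cv) / (n - 3))
  q <- -qnorm((1 - conf_level) / 2)
  l1 <- tanh(z1 - q / sqrt(n - 3)); u1 <- tanh(z1 + q / sqrt(n - 3))
  l2 <- tanh(z2 - q / sqrt(n - 3)); u2 <- tanh(z2 + q / sqrt(n - 3))
  dif <- r1 - r2
  lo <- dif - sqrt((r1 - l1)^2 + (u2 - r2)^2 - 2 * cv * (r1 - l1) * (u2 - r2))
  hi <- dif + sqrt((u1 - r1)^2 + (r2 - l2)^2 - 2 * cv * (u1 - r1) * (r2 - l2))
  list(z = z, p_value = 2 * pnorm(-abs(z)), ci_lower = lo, ci_upper = hi)
}

#' Cross-correlation between two class-wise reference profiles
#'
#' Helper for [compare_dependent_correlations()]: correlates the sexual
#' female reference profiles of two gene classes, equalising lengths by
#' random subsampling of the larger class under a fixed seed.
#'
#' @param logtpm log2(TPM+1) matrix.
#' @param design Sample sheet.
#' @param species Species.
#' @param genes_a,genes_b The two gene sets.
#' @param seed Seed for the subsampling. Default 1.
#' @return Pearson correlation (numeric scalar).
#' @export
profile_cross_correlation <- function(logtpm, design, species,
                                      genes_a, genes_b, seed = 1) {
  grp <- .sbg_samples(design, species)
  genes_a <- intersect(genes_a, rownames(logtpm))
  genes_b <- intersect(genes_b, rownames(logtpm))
  n <- min(length(genes_a), length(genes_b))
  if (n < 3) .stopf("need at least 3 genes per set")
  set.seed(seed)
  if (length(genes_a) > n) genes_a <- sample(genes_a, n)
  if (length(genes_b) > n) genes_b <- sample(genes_b, n)
  a <- rowMeans(logtpm[genes_a, grp$female, drop = FALSE])
  b <- rowMeans(logtpm[genes_b, grp$female, drop = FALSE])
  cor(sort(a), sort(b))
}

#' Regression-to-the-mean control
#'
#' Calls sex-biased genes in a male-vs-Amazon contrast, takes the
#' male-biased set from that contrast, and tests its expression shift
#' between sexual females and Amazons: under a pure regression-to-the-mean
#' artefact this control set behaves like the original male-biased set.
#'
#' @param cm A [count_matrix()].
#' @param logtpm log2(TPM+1) matrix.
#' @param design Sample sheet.
#' @param species Species.
#' @param expressed Gene ids to test in the male-vs-Amazon contrast.
#' @param alpha,lfc_min Thresholds passed to the bias caller.
#' @return List: `n_control_genes`, `shift` (the class_shift_test row for
#'   the control set, or NULL), `direction` ("higher_in_female",
#'   "higher_in_amazon" or NA), `empty` flag.
#' @export
rtm_control <- function(cm, logtpm, design, species, expressed = NULL,
                        alpha = 0.05, lfc_min = 1) {
  grp <- .sbg_samples(design, species)
  if (length(grp$male) == 0 || length(grp$female) == 0 ||
      length(grp$amazon) == 0)
    .stopf("species %s needs male, female and amazon samples", species)
  # male vs Amazon contrast: relabel amazons as the reference "female" side
  sub <- design[design$sample_id %in% c(grp$male, grp$amazon), , drop = FALSE]
  sub$mode <- "sexual"
  sub$sex[sub$sample_id %in% grp$amazon] <- "female"
  bt <- call_sex_biased(cm, sub, species, expressed = expressed,
                        alpha = alpha, lfc_min = lfc_min)
  ctrl <- bias_class_genes(bt, "male_biased")
  if (length(ctrl) == 0)
    return(list(n_control_genes = 0L, shift = NULL, direction = NA,
                empty = TRUE))
  fake_bias <- data.frame(gene_id = ctrl, log2fc = 1, p_value = 0,
                          p_adj = 0, bias_class = "male_biased",
                          stringsAsFactors = FALSE)
  class(fake_bias) <- c("bias_table", "data.frame")
  shift <- class_shift_test(logtpm, fake_bias, design, species,
                            classes = "male_biased")
  direction <- if (shift$median_female > shift$median_amazon)
    "higher_in_female" else "higher_in_amazon"
  list(n_control_genes = length(ctrl), shift = shift,
       direction = direction, empty = FALSE)
}
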