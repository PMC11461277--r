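# Sex-biased gene calling: per-gene NB GLM contrasting male vs female
# samples of the sexual populations, Wald (default) or LRT on the sex term,
# BH correction, and the FC >= 2 / p_adj < 0.05 classification rule.

# Generic two-group DE engine shared by call_sex_biased and the
# regression-to-the-mean control. `group` is a factor with the reference
# level first; positive log2fc means higher expression in the second level.
.de_two_group <- function(counts, group, population = NULL, offsets,
                          genes, test = c("wald", "lrt")) {
  test <- match.arg(test)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) .stopf("exactly two groups are required")
  if (any(table(group) < 2)) .stopf("each group needs at least 2 samples")
  if (!is.null(population) && length(unique(population)) > 1) {
    X <- model.matrix(~ population + group,
                      data.frame(population = factor(population),
                                 group = group))
  } else {
    X <- model.matrix(~ group, data.frame(group = group))
  }
  gcol <- paste0("group", levels(group)[2])
  res <- data.frame(gene_id = genes, log2fc = NA_real_,
                    p_value = NA_real_, dispersion = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  loff <- log(offsets)
  for (i in seq_along(genes)) {
    y <- counts[genes[i], ]
    if (all(y == 0)) next
    fit <- tryCatch(fit_nb_glm(y, X, offset = loff), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    res$dispersion[i] <- fit$dispersion
    res$converged[i] <- TRUE
    res$log2fc[i] <- fit$coefficients[[gcol]] / log(2)
    if (test == "wald") {
      res$p_value[i] <- nb_wald_test(fit, gcol)$p_value
    } else {
      Xr <- X[, setdiff(colnames(X), gcol), drop = FALSE]
      red <- tryCatch(fit_nb_glm(y, Xr, offset = loff,
                                 dispersion = fit$dispersion),
                      error = function(e) NULL)
      if (!is.null(red)) res$p_value[i] <- nb_lrt(fit, red)$p_value
    }
  }
  n_bad <- sum(!res$converged)
  if (n_bad > 0)
    warning(sprintf("%d gene(s) excluded (all-zero or non-converged fit)",
                    n_bad), call. = FALSE)
  res
}

#' Call sex-biased genes in the sexual populations of one species
#'
#' Per expressed gene, a negative binomial GLM with log size-factor offsets
#' contrasts male vs female gamete samples of the sexual populations
#' (population as an additive covariate when more than one is pooled).
#' A gene is classified as biased when the BH-adjusted p-value is below
#' `alpha` and |log2 fold change| is at least `lfc_min` (fold change >= 2
#' at the default); the sign gives the direction (positive = male-biased).
#'
#' @param cm A [count_matrix()] for the species.
#' @param design Sample sheet; automatically restricted to sexual
#'   gametophyte gamete samples of `species`.
#' @param species Species identifier to analyse.
#' @param expressed Character vector of gene ids to test (e.g. from
#'   [expressed_genes()]); defaults to all genes.
#' @param alpha Adjusted p-value cut-off. Default 0.05.
#' @param lfc_min Minimum |log2 fold change|. Default 1.
#' @param pool_populations Pool sexual populations with a population
#'   covariate (default) or require a single population.
#' @param test "wald" (default) or "lrt" on the sex term.
#' @return A `bias_table` data.frame: gene_id, log2fc, p_value, p_adj,
#'   bias_class in {female_biased, male_biased, unbiased}.
#' @export
call_sex_biased <- function(cm, design, species, expressed = NULL,
                            alpha = 0.05, lfc_min = 1,
                            pool_populations = TRUE,
                            test = c("wald", "lrt")) {
  validate_sample_sheet(design)
  sub <- design[design$species == species & design$mode == "sexual" &
                  design$generation == "gametophyte", , drop = FALSE]
  if ("tissue" %in% names(sub))
    sub <- sub[sub$tissue == "gamete", , drop = FALSE]
  if (!all(c("female", "male") %in% sub$sex))
    .stopf("both sexes are required for species %s", species)
  if (!pool_populations && length(unique(sub$population)) > 1)
    .stopf("multiple sexual populations present; set pool_populations=TRUE")
  counts <- cm$counts[, sub$sample_id, drop = FALSE]
  if (is.null(expressed)) expressed <- rownames(counts)
  expressed <- intersect(expressed, rownames(counts))
  sf <- size_factors(cm, sub$sample_id)
  res <- .de_two_group(counts,
                       group = factor(sub$sex, levels = c("female", "male")),
                       population = sub$population, offsets = sf,
                       genes = expressed, test = test)
  res$p_adj <- bh_adjust(res$p_value)
  res$bias_class <- "unbiased"
  hit <- !is.na(res$p_adj) & res$p_adj < alpha &
    !is.na(res$log2fc) & abs(res$log2fc) >= lfc_min
  res$bias_class[hit & res$log2fc > 0] <- "male_biased"
  res$bias_class[hit & res$log2fc < 0] <- "female_biased"
  res <- res[, c("gene_id", "log2fc", "p_value", "p_adj", "bias_class",
                 "dispersion", "converged")]
  class(res) <- c("bias_table", "data.frame")
  res
}

#' Genes of one bias class
#'
#' @param bias_table A `bias_table` from [call_sex_biased()].
#' @param class One of "female_biased", "male_biased", "unbiased".
#' @return Character vector of gene ids.
#' @export
bias_class_genes <- function(bias_table, class) {
  stopifnot(class %in% c("female_biased", "male_biased", "unbiased"))
  bias_table$gene_id[bias_table$bias_class == class]
}
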