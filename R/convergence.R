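# Convergent expression shifts across two independent transitions to
# asexuality: per single-copy orthologue (SCO), an NB GLM with terms
# species + mode + species:mode on pooled female/Amazon samples of both
# species; a SCO is convergent when the reproductive-mode term is
# significant but neither the species term nor the interaction is.

# Assemble joined SCO counts, offsets and factors once; reused by the
# permutation engine.
.convergence_inputs <- function(cm1, cm2, ortho, design, species) {
  validate_sample_sheet(design)
  validate_ortho_map(ortho)
  if (length(species) != 2) .stopf("species must name the two species")
  sub <- design[design$generation == "gametophyte" &
                  design$species %in% species, , drop = FALSE]
  if ("tissue" %in% names(sub))
    sub <- sub[sub$tissue == "gamete", , drop = FALSE]
  sub <- sub[!is.na(sub$sex) & sub$sex == "female", , drop = FALSE]
  for (sp in species) {
    m <- sub$mode[sub$species == sp]
    if (!all(c("sexual", "amazon") %in% m))
      .stopf("species %s must contribute sexual-female and amazon samples",
             sp)
  }
  s1 <- sub$sample_id[sub$species == species[1]]
  s2 <- sub$sample_id[sub$species == species[2]]
  J <- cbind(cm1$counts[ortho$gene_id_species1, s1, drop = FALSE],
             cm2$counts[ortho$gene_id_species2, s2, drop = FALSE])
  rownames(J) <- ortho$sco_id
  sf <- c(size_factors(cm1, s1), size_factors(cm2, s2))
  ord <- match(c(s1, s2), sub$sample_id)
  list(J = J, loff = log(sf),
       species_f = factor(sub$species[ord], levels = species),
       mode_f = factor(sub$mode[ord], levels = c("sexual", "amazon")),
       block = paste(sub$species[ord], sub$population[ord], sub$sex[ord],
                     sep = "/"),
       design = sub[ord, , drop = FALSE])
}

.convergence_engine <- function(J, loff, species_f, mode_f, alpha = 0.05,
                                use_adjusted = TRUE) {
  df <- data.frame(species = species_f, mode = mode_f)
  # sum-to-zero coding for species so the mode term is the average Amazon
  # shift across species and the table is invariant to which species is
  # "species 1" (the species coefficient just flips sign)
  X <- model.matrix(~ species + mode + species:mode, df,
                    contrasts.arg = list(species = "contr.sum"))
  term_cols <- c(species = 2L, mode = 3L, interaction = 4L)
  n <- nrow(J)
  out <- data.frame(sco_id = rownames(J),
                    lrt_species = NA_real_, p_species = NA_real_,
                    lrt_mode = NA_real_, p_mode = NA_real_,
                    lrt_interaction = NA_real_, p_interaction = NA_real_,
                    mode_log2fc = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE)
  sp1 <- species_f == levels(species_f)[1]
  for (i in seq_len(n)) {
    y <- J[i, ]
    if (all(y[sp1] == 0) || all(y[!sp1] == 0)) next
    full <- .nbglm_fit_cpp(y, X, loff, max((var(y) - mean(y)) / mean(y)^2,
                                           0.01),
                           TRUE, 1e-8, 50L, 1e-8, TRUE)
    if (!full$converged) next
    out$tested[i] <- TRUE
    out$mode_log2fc[i] <- full$beta[term_cols[["mode"]]] / log(2)
    for (term in names(term_cols)) {
      Xr <- X[, -term_cols[[term]], drop = FALSE]
      red <- .nbglm_fit_cpp(y, Xr, loff, full$alpha, FALSE, 1e-8, 50L, 1e-8,
                            FALSE)
      stat <- max(0, 2 * (full$loglik - red$loglik))
      out[[paste0("lrt_", term)]][i] <- stat
      out[[paste0("p_", term)]][i] <- pchisq(stat, 1, lower.tail = FALSE)
    }
  }
  for (term in names(term_cols))
    out[[paste0("padj_", term)]] <- bh_adjust(out[[paste0("p_", term)]])
  pick <- if (use_adjusted) function(t) out[[paste0("padj_", t)]] else
    function(t) out[[paste0("p_", t)]]
  out$convergent <- out$tested &
    !is.na(pick("mode")) & pick("mode") < alpha &
    !is.na(pick("species")) & pick("species") >= alpha &
    !is.na(pick("interaction")) & pick("interaction") >= alpha
  out$direction <- ifelse(out$convergent,
                          ifelse(out$mode_log2fc > 0, "up_in_amazon",
                                 "down_in_amazon"), NA_character_)
  class(out) <- c("convergence_table", "data.frame")
  out
}

#' Call convergent expression shifts across two species
#'
#' For each SCO, pooled counts of sexual-female and Amazon gamete samples of
#' both species (males excluded) are modelled with an NB GLM with terms
#' species + mode + species:mode and per-sample log size-factor offsets
#' (computed within species). Three drop-one-term likelihood ratio tests are
#' BH-adjusted per term across SCOs; a SCO is flagged convergent when the
#' mode term is significant and neither species nor interaction is.
#'
#' @param cm1,cm2 [count_matrix()] for species 1 and 2 (matching
#'   `gene_id_species1` / `gene_id_species2` of `ortho`).
#' @param ortho Orthologue map (see [read_ortho_map()]).
#' @param design Sample sheet covering both species.
#' @param species Length-2 character vector naming species 1 and 2.
#' @param expressed_sco Optional SCO ids to test (defaults to all in
#'   `ortho`). SCOs that are all-zero in a species are skipped.
#' @param alpha Significance threshold on each term. Default 0.05.
#' @param use_adjusted Use BH-adjusted p-values for all three terms
#'   (default); FALSE switches to raw p-values.
#' @return A `convergence_table` data.frame with per-term LRT statistics,
#'   raw and adjusted p-values, `convergent` flag and `direction`
#'   (up_in_amazon / down_in_amazon, defined for convergent SCOs only).
#' @export
call_convergent <- function(cm1, cm2, ortho, design, species,
                            expressed_sco = NULL, alpha = 0.05,
                            use_adjusted = TRUE) {
  if (!is.null(expressed_sco))
    ortho <- ortho[ortho$sco_id %in% expressed_sco, , drop = FALSE]
  inp <- .convergence_inputs(cm1, cm2, ortho, design, species)
  .convergence_engine(inp$J, inp$loff, inp$species_f, inp$mode_f,
                      alpha = alpha, use_adjusted = use_adjusted)
}

#' Block-constrained permutation null for the convergent-SCO count
#'
#' The permutation unit is the (species, population, sex) block: within each
#' species, reproductive-mode labels are shuffled across blocks, preserving
#' the original number of sexual and Amazon blocks, so replicates of one
#' population never receive different labels. The convergence caller is
#' re-run on each permuted design and the empirical p-value uses the
#' add-one convention `(1 + #{null >= observed}) / (B + 1)`.
#'
#' @inheritParams call_convergent
#' @param B Number of permutations.
#' @param seed Integer RNG seed.
#' @return A `permutation_result` list: `observed_count`, `null_counts`,
#'   `empirical_p`, `B`, `seed`.
#' @export
permutation_null <- function(cm1, cm2, ortho, design, species, B, seed,
                             expressed_sco = NULL, alpha = 0.05,
                             use_adjusted = TRUE) {
  if (!is.null(expressed_sco))
    ortho <- ortho[ortho$sco_id %in% expressed_sco, , drop = FALSE]
  inp <- .convergence_inputs(cm1, cm2, ortho, design, species)
  blocks <- unique(data.frame(block = inp$block,
                              species = as.character(inp$species_f),
                              mode = as.character(inp$mode_f),
                              stringsAsFactors = FALSE))
  for (sp in levels(inp$species_f)) {
    bs <- blocks[blocks$species == sp, ]
    if (nrow(bs) < 2 || length(unique(bs$mode)) < 2)
      .stopf("species %s has too few population blocks to permute", sp)
  }
  obs_tab <- .convergence_engine(inp$J, inp$loff, inp$species_f, inp$mode_f,
                                 alpha, use_adjusted)
  observed <- sum(obs_tab$convergent)
  set.seed(seed)
  null_counts <- integer(B)
  for (b in seq_len(B)) {
    repeat {
      perm_mode <- blocks$mode
      for (sp in levels(inp$species_f)) {
        idx <- which(blocks$species == sp)
        perm_mode[idx] <- sample(blocks$mode[idx])
      }
      degen <- vapply(levels(inp$species_f), function(sp) {
        length(unique(perm_mode[blocks$species == sp])) < 2
      }, logical(1))
      if (!any(degen)) break
    }
    mode_b <- factor(perm_mode[match(inp$block, blocks$block)],
                     levels = c("sexual", "amazon"))
    tab <- .convergence_engine(inp$J, inp$loff, inp$species_f, mode_b,
                               alpha, use_adjusted)
    null_counts[b] <- sum(tab$convergent)
  }
  structure(list(observed_count = observed, null_counts = null_counts,
                 empirical_p = (1 + sum(null_counts >= observed)) / (B + 1),
                 B = B, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed = %d, B = %d, empirical p = %.4g\n",
    x$observed_count, x$B, x$empirical_p))
  invisible(x)
}

#' Exact multiset intersection test
#'
#' Upper-tail exact probability that k fixed-size sets drawn independently
#' and uniformly from a universe intersect in at least the observed number
#' of elements. For k = 2 this is the hypergeometric tail; for k > 2 the
#' exact distribution is obtained by convolving the pairwise kernel.
#'
#' @param sets List of 2 or more character vectors (subsets of the
#'   universe).
#' @param universe_size Size of the universe.
#' @return List with `observed` intersection size and upper-tail `p_value`.
#' @export
intersection_test <- function(sets, universe_size) {
  if (length(sets) < 2) .stopf("at least two sets are required")
  sizes <- lengths(sets)
  if (any(sizes > universe_size)) .stopf("a set is larger than the universe")
  if (length(unique(unlist(sets))) > universe_size)
    .stopf("universe_size smaller than the union of the sets")
  observed <- length(Reduce(intersect, sets))
  # distribution of the running intersection size
  dist <- c(rep(0, sizes[1]), 1)  # point mass at |set 1|
  for (k in 2:length(sets)) {
    nk <- sizes[k]
    new <- rep(0, universe_size + 1)
    for (m in which(dist > 0) - 1) {
      j <- 0:min(m, nk)
      new[j + 1] <- new[j + 1] +
        dist[m + 1] * dhyper(j, m, universe_size - m, nk)
    }
    dist <- new
  }
  p <- sum(dist[(observed + 1):length(dist)])
  list(observed = observed, p_value = min(1, p))
}

#' Convergent fraction as a percentage
#'
#' @param n_convergent Number of convergent SCOs.
#' @param n_expressed Number of expressed SCOs tested.
#' @return `100 * n_convergent / n_expressed`.
#' @export
convergent_fraction <- function(n_convergent, n_expressed) {
  if (n_expressed <= 0) .stopf("n_expressed must be positive")
  100 * n_convergent / n_expressed
}
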