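# End-to-end orchestration: expression core -> sex bias -> convergence ->
# sex-biased gene fate -> diversity -> Amazon candidates -> divergence
# rates, from a single configuration (synthetic fixture mode or user
# files), with per-stage TSV outputs and a JSON summary.

#' Pipeline configuration
#'
#' All thresholds default to the field-standard values for this analysis: 0.4 TPM expression
#' threshold over two-thirds of samples, 2-fold change at adjusted p <
#' 0.05 for sex bias, candidate depth 9 with 7 alt-supporting reads,
#' diversity coverage 7 at site quality 20, and the 0 < dS < 2 validity
#' window.
#'
#' @param sim A [simulation_config()] for fixture mode, or NULL when
#'   `paths` is given.
#' @param paths Named list of input files (counts1, counts2, samples,
#'   ortho, gff1, gff2, cds1, cds2, vcf1, vcf2) for file mode.
#' @param tpm_threshold,expressed_fraction Expressed-gene rule.
#' @param lfc_min Minimum |log2 FC| for sex bias (1 = 2-fold).
#' @param p_adj Adjusted-p cut-off used throughout.
#' @param candidate_depth,candidate_alt_reads Amazon cascade thresholds.
#' @param diversity_coverage,diversity_qual,diversity_carriers Diversity
#'   filter thresholds.
#' @param B Permutations for the convergence null.
#' @param seed Seed governing all stochastic stages.
#' @param out_dir Output directory (NULL = no files written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(), paths = NULL,
                            tpm_threshold = 0.4,
                            expressed_fraction = 2 / 3,
                            lfc_min = 1, p_adj = 0.05,
                            candidate_depth = 9, candidate_alt_reads = 7,
                            diversity_coverage = 7, diversity_qual = 20,
                            diversity_carriers = 2,
                            B = 10000, seed = 1, out_dir = NULL) {
  for (v in c(tpm_threshold, lfc_min, p_adj, candidate_depth,
              candidate_alt_reads, diversity_coverage, diversity_qual,
              diversity_carriers, B))
    if (v <= 0) .stopf("configuration error: thresholds must be positive")
  structure(list(sim = sim, paths = paths,
                 tpm_threshold = tpm_threshold,
                 expressed_fraction = expressed_fraction,
                 lfc_min = lfc_min, p_adj = p_adj,
                 candidate_depth = candidate_depth,
                 candidate_alt_reads = candidate_alt_reads,
                 diversity_coverage = diversity_coverage,
                 diversity_qual = diversity_qual,
                 diversity_carriers = diversity_carriers,
                 B = B, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a flat key = value pipeline configuration file
#'
#' TOML-style flat syntax: one `key = value` per line, `#` comments,
#' strings optionally quoted. Unknown keys are errors. Keys prefixed
#' `sim.` are passed to [simulation_config()].
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      .stopf("malformed config line: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("^\"|\"$", "", val)
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  sim_keys <- grep("^sim\\.", names(kv), value = TRUE)
  path_keys <- grep("^path\\.", names(kv), value = TRUE)
  pc_formals <- setdiff(names(formals(pipeline_config)), c("sim", "paths"))
  other <- setdiff(names(kv), c(sim_keys, path_keys))
  bad <- setdiff(other, pc_formals)
  if (length(bad) > 0) .stopf("unknown config key(s): %s",
                              paste(bad, collapse = ", "))
  sim_args <- setNames(kv[sim_keys], sub("^sim\\.", "", sim_keys))
  bad_sim <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad_sim) > 0) .stopf("unknown config key(s): sim.%s",
                                  paste(bad_sim, collapse = ", "))
  args <- kv[other]
  args$sim <- do.call(simulation_config, sim_args)
  if (length(path_keys) > 0)
    args$paths <- setNames(kv[path_keys], sub("^path\\.", "", path_keys))
  do.call(pipeline_config, args)
}

.load_dataset <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    design <- read_sample_sheet(p$samples)
    species <- unique(design$species)
    ann <- list(read_annotation(p$gff1, p$cds1),
                read_annotation(p$gff2, p$cds2))
    names(ann) <- species
    cnt <- list(read_counts(p$counts1), read_counts(p$counts2))
    names(cnt) <- species
    vars <- list(read_vcf(p$vcf1), read_vcf(p$vcf2))
    names(vars) <- species
    list(design = design, ortho = read_ortho_map(p$ortho),
         annotation = ann, counts = cnt, variants = vars, truth = NULL)
  } else {
    simulate_bundle(config$sim)
  }
}

.gamete_samples <- function(design, sp) {
  sub <- design[design$species == sp & design$generation == "gametophyte", ]
  if ("tissue" %in% names(sub)) sub <- sub[sub$tissue == "gamete", ]
  sub
}

#' Run the full pipeline
#'
#' Executes expression filtering, sex-bias calling, convergence detection
#' with its permutation null, the sex-biased-gene fate analyses, the
#' diversity models, the Amazon-candidate cascade with cross-species
#' intersection and the orthologue divergence rates. When `out_dir` is set,
#' per-stage TSVs, a JSON summary and a run log are written.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with all stage tables and the `summary` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load_inputs"
  on.exit(if (!is.null(stage))
    message(sprintf("pipeline aborted in stage '%s'", stage)))
  ds <- .load_dataset(config)
  species <- unique(ds$design$species)
  res <- list(species = species)
  summary <- list()

  stage <- "expression_and_sex_bias"
  per_species <- list()
  for (sp in species) {
    cm <- ds$counts[[sp]]
    tpm <- compute_tpm(cm)
    ltpm <- log_tpm(tpm)
    gam <- .gamete_samples(ds$design, sp)
    expressed <- expressed_genes(tpm, gam$sample_id,
                                 threshold = config$tpm_threshold,
                                 fraction = config$expressed_fraction)
    bias <- call_sex_biased(cm, ds$design, sp, expressed = expressed,
                            alpha = config$p_adj, lfc_min = config$lfc_min)
    per_species[[sp]] <- list(tpm = tpm, ltpm = ltpm,
                              expressed = expressed, bias = bias)
    summary[[sp]] <- list(
      n_expressed = length(expressed),
      n_female_biased = sum(bias$bias_class == "female_biased"),
      n_male_biased = sum(bias$bias_class == "male_biased"))
  }

  # convergence across the two transitions
  stage <- "convergence"
  sp1 <- species[1]; sp2 <- species[2]
  expressed_sco <- ds$ortho$sco_id[
    ds$ortho$gene_id_species1 %in% per_species[[sp1]]$expressed &
      ds$ortho$gene_id_species2 %in% per_species[[sp2]]$expressed]
  conv <- call_convergent(ds$counts[[sp1]], ds$counts[[sp2]], ds$ortho,
                          ds$design, species,
                          expressed_sco = expressed_sco,
                          alpha = config$p_adj)
  perm <- permutation_null(ds$counts[[sp1]], ds$counts[[sp2]], ds$ortho,
                           ds$design, species, B = config$B,
                           seed = config$seed,
                           expressed_sco = expressed_sco,
                           alpha = config$p_adj)
  n_conv <- sum(conv$convergent)
  summary$convergence <- list(
    n_expressed_sco = length(expressed_sco),
    n_convergent = n_conv,
    convergent_fraction_pct = convergent_fraction(n_conv,
                                                  length(expressed_sco)),
    permutation_p = perm$empirical_p,
    permutation_B = perm$B)

  # sex-biased genes among convergent SCOs (exact intersection test)
  sbg1 <- c(bias_class_genes(per_species[[sp1]]$bias, "female_biased"),
            bias_class_genes(per_species[[sp1]]$bias, "male_biased"))
  sbg2 <- c(bias_class_genes(per_species[[sp2]]$bias, "female_biased"),
            bias_class_genes(per_species[[sp2]]$bias, "male_biased"))
  sbg_sco <- ds$ortho$sco_id[ds$ortho$gene_id_species1 %in% sbg1 |
                               ds$ortho$gene_id_species2 %in% sbg2]
  sbg_sco <- intersect(sbg_sco, expressed_sco)
  conv_sco_ids <- conv$sco_id[conv$convergent]
  summary$intersection <- if (length(sbg_sco) > 0 &&
                              length(conv_sco_ids) > 0) {
    it <- intersection_test(list(sbg_sco, conv_sco_ids),
                            universe_size = length(expressed_sco))
    list(observed = it$observed, p_value = it$p_value)
  } else list(observed = 0L, p_value = NA_real_)

  # fate of sex-biased genes
  stage <- "sbg_fate"
  for (sp in species) {
    ps <- per_species[[sp]]
    shift <- class_shift_test(ps$ltpm, ps$bias, ds$design, sp)
    simil <- similarity_index(ps$ltpm, ps$bias, ds$design, sp)
    per_species[[sp]]$class_shift <- shift
    per_species[[sp]]$similarity <- simil
    depcor <- NULL
    fbg <- bias_class_genes(ps$bias, "female_biased")
    unb <- bias_class_genes(ps$bias, "unbiased")
    if (!is.null(simil) && length(fbg) >= 3 && length(unb) >= 3) {
      r_f <- mean(simil$pearson_r[simil$bias_class == "female_biased"],
                  na.rm = TRUE)
      r_u <- mean(simil$pearson_r[simil$bias_class == "unbiased"],
                  na.rm = TRUE)
      rc <- profile_cross_correlation(ps$ltpm, ds$design, sp, fbg, unb,
                                      seed = config$seed)
      n_eff <- min(length(fbg), length(unb))
      if (abs(r_f) < 1 && abs(r_u) < 1 && n_eff >= 4)
        depcor <- compare_dependent_correlations(r_f, r_u, n_eff, rc)
    }
    rtm <- tryCatch(rtm_control(ds$counts[[sp]], ps$ltpm, ds$design, sp,
                                expressed = ps$expressed,
                                alpha = config$p_adj,
                                lfc_min = config$lfc_min),
                    error = function(e) NULL)
    per_species[[sp]]$rtm <- rtm
    sm <- summary[[sp]]
    sh_f <- shift[shift$bias_class == "female_biased", ]
    sm$fbg_shift_p <- if (nrow(sh_f) > 0) sh_f$p_value else NA_real_
    sm$fbg_median_female <- if (nrow(sh_f) > 0) sh_f$median_female else NA
    sm$fbg_median_amazon <- if (nrow(sh_f) > 0) sh_f$median_amazon else NA
    if (!is.null(simil)) {
      for (cl in unique(simil$bias_class))
        sm[[paste0("similarity_r_", cl)]] <-
          mean(simil$pearson_r[simil$bias_class == cl], na.rm = TRUE)
    }
    if (!is.null(depcor)) sm$depcor_p <- depcor$p_value
    if (!is.null(rtm) && !rtm$empty) {
      sm$rtm_direction <- rtm$direction
      sm$rtm_p <- rtm$shift$p_value
    }
    summary[[sp]] <- sm
  }

  # diversity and selection efficacy
  stage <- "popgen_diversity"
  for (sp in species) {
    ps <- per_species[[sp]]
    gam <- .gamete_samples(ds$design, sp)
    vt <- ds$variants[[sp]]
    ann <- ds$annotation[[sp]]
    div <- list()
    for (pop in unique(gam$population)) {
      samp <- gam$sample_id[gam$population == pop]
      if (length(samp) < 2) next
      fv <- filter_variants_diversity(vt, samp,
                                      min_carriers = config$diversity_carriers,
                                      min_dp = config$diversity_coverage,
                                      min_qual = config$diversity_qual)
      d <- gene_diversity(fv, ann, samp, group = pop,
                          min_dp = config$diversity_coverage)
      d$mode <- gam$mode[gam$population == pop][1]
      d <- d[d$gene_id %in% ps$expressed, , drop = FALSE]
      lt <- rowMeans(ps$ltpm[d$gene_id, samp, drop = FALSE])
      d$log_expr <- lt
      div[[pop]] <- d
    }
    div <- do.call(rbind, div)
    per_species[[sp]]$diversity <- div
    sm <- summary[[sp]]
    pis_dat <- data.frame(value = div$pi_s, mode = div$mode,
                          gene = div$gene_id, log_expr = div$log_expr)
    sm$pis_lmm_p <- tryCatch(lmm_group_test(pis_dat)$p_value,
                             error = function(e) NA_real_)
    sm$pis_sexual <- mean(div$pi_s[div$mode == "sexual"])
    sm$pis_amazon <- mean(div$pi_s[div$mode == "amazon"])
    rat <- div[!is.na(div$pi_ratio), , drop = FALSE]
    if (nrow(rat) > 3) {
      rat_dat <- data.frame(value = rat$pi_ratio, mode = rat$mode,
                            gene = rat$gene_id, log_expr = rat$log_expr)
      sm$ratio_lmm_p <- tryCatch(lmm_group_test(rat_dat)$p_value,
                                 error = function(e) NA_real_)
      sm$ratio_sexual <- mean(rat$pi_ratio[rat$mode == "sexual"])
      sm$ratio_amazon <- mean(rat$pi_ratio[rat$mode == "amazon"])
    }
    snp_dat <- data.frame(successes = as.integer(div$n_snps > 0),
                          totals = 1L, mode = div$mode,
                          gene = div$gene_id, log_expr = div$log_expr)
    sm$snp_presence_p <- tryCatch(binomial_snp_models(snp_dat)$p_value,
                                  error = function(e) NA_real_)
    vs <- div[div$n_snps > 0, , drop = FALSE]
    if (nrow(vs) > 3) {
      vs_dat <- data.frame(successes = vs$n_variable_sites,
                           totals = vs$cds_len, mode = vs$mode,
                           gene = vs$gene_id, log_expr = vs$log_expr)
      sm$variable_sites_p <- tryCatch(binomial_snp_models(vs_dat)$p_value,
                                      error = function(e) NA_real_)
    }

    # haploid-specific genes vs non-specific (sexual populations pooled)
    gen <- ds$design[ds$design$species == sp &
                       ds$design$population == "genlib", , drop = FALSE]
    if (nrow(gen) > 0) {
      hap <- haploid_specific_genes(ps$tpm, gen,
                                    threshold = config$tpm_threshold)
      sx <- gam$sample_id[gam$mode == "sexual"]
      fvx <- filter_variants_diversity(vt, sx,
                                       min_carriers = config$diversity_carriers,
                                       min_dp = config$diversity_coverage,
                                       min_qual = config$diversity_qual)
      dx <- gene_diversity(fvx, ann, sx, group = "sexual_pooled",
                           min_dp = config$diversity_coverage)
      ratios <- setNames(dx$pi_ratio, dx$gene_id)
      nonspec <- setdiff(ps$expressed, hap)
      cgc <- compare_gene_classes(ratios, hap, nonspec)
      per_species[[sp]]$haploid_specific <- hap
      sm$n_haploid_specific <- length(hap)
      sm$hapspec_mean_ratio <- cgc$mean_a
      sm$nonspec_mean_ratio <- cgc$mean_b
      sm$hapspec_vs_nonspec_p <- cgc$p_value
    }
    summary[[sp]] <- sm
  }

  # Amazon candidate cascade and cross-species intersection
  stage <- "amazon_variants"
  cands <- list()
  for (sp in species) {
    cands[[sp]] <- candidate_cascade(ds$variants[[sp]], ds$design,
                                     ds$annotation[[sp]], sp,
                                     min_dp = config$candidate_depth,
                                     min_alt_reads = config$candidate_alt_reads)
    summary[[sp]]$n_candidates <- nrow(cands[[sp]])
    summary[[sp]]$n_missense_candidates <-
      sum(cands[[sp]]$effect == "nonsynonymous")
  }
  shared <- cross_species_candidates(cands[[sp1]], cands[[sp2]], ds$ortho)
  summary$shared_candidates <- list(n = nrow(shared),
                                    sco_ids = shared$sco_id)

  # divergence rates on orthologues
  stage <- "divergence_rates"
  dnds <- dnds_orthologs(ds$annotation[[sp1]]$cds, ds$annotation[[sp2]]$cds,
                         ds$ortho)
  conv_class <- setNames(ifelse(ds$ortho$sco_id %in% conv_sco_ids,
                                "convergent", "non_convergent"),
                         ds$ortho$sco_id)
  rates <- tryCatch(rates_by_class(dnds, conv_class),
                    error = function(e) NULL)
  summary$dnds <- list(
    n_valid = sum(dnds$valid),
    mean_omega = mean(dnds$omega[dnds$valid], na.rm = TRUE))
  if (!is.null(rates)) {
    r1 <- rates[1, ]
    summary$dnds$mean_omega_convergent <-
      if (r1$class_a == "convergent") r1$mean_a else r1$mean_b
    summary$dnds$mean_omega_non_convergent <-
      if (r1$class_a == "non_convergent") r1$mean_a else r1$mean_b
    summary$dnds$convergent_vs_rest_p <- r1$p_value
  }

  res$per_species <- per_species
  res$convergence <- conv
  res$permutation <- perm
  res$candidates <- cands
  res$shared_candidates <- shared
  res$dnds <- dnds
  res$summary <- summary
  res$truth <- ds$truth

  stage <- "report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    wt <- function(df, fn) write.table(df, file.path(od, fn), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
    for (sp in species) {
      wt(per_species[[sp]]$bias, sprintf("bias_%s.tsv", sp))
      wt(per_species[[sp]]$class_shift, sprintf("class_shift_%s.tsv", sp))
      if (!is.null(per_species[[sp]]$similarity))
        wt(per_species[[sp]]$similarity, sprintf("similarity_%s.tsv", sp))
      if (!is.null(per_species[[sp]]$diversity))
        wt(per_species[[sp]]$diversity, sprintf("diversity_%s.tsv", sp))
      wt(as.data.frame(cands[[sp]]), sprintf("candidates_%s.tsv", sp))
    }
    wt(as.data.frame(conv), "convergence.tsv")
    wt(shared, "shared_candidates.tsv")
    wt(as.data.frame(dnds), "dnds.tsv")
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    log <- c(sprintf("amazonswitch %s",
                     as.character(utils::packageVersion("amazonswitch"))),
             R.version.string,
             sprintf("seed: %d", config$seed),
             sprintf("B: %d", config$B),
             sprintf("thresholds: tpm>%g, |lfc|>=%g, p_adj<%g, depth>=%g, alt>=%g",
                     config$tpm_threshold, config$lfc_min, config$p_adj,
                     config$candidate_depth, config$candidate_alt_reads),
             sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
    writeLines(log, file.path(od, "run_log.txt"))
  }
  stage <- NULL
  invisible(res)
}
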