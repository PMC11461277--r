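# Ground-truth-labelled synthetic data emulating the study design: two
# species, sexual populations contributing male and female gamete samples,
# Amazon populations contributing female-only samples, generation-specific
# gametophyte/sporophyte libraries, negative binomially distributed counts
# with planted sex-biased and convergent genes, random-sense-codon CDS
# models, and haploid variant tables with planted diversity contrasts and
# Amazon-fixed missense candidates.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: 2 species, 2 sexual and 2
#' Amazon populations per species with 3 replicate gamete libraries each,
#' 3 gametophyte libraries per sex plus 3 sporophyte libraries per species,
#' NB counts (variance = mu + dispersion * mu^2), planted sex-biased genes
#' (<1% of genes), 6.7% convergent SCOs, and a 5:1 sexual:Amazon per-site
#' diversity contrast.
#'
#' @param populations_per_mode Populations per species per reproductive
#'   mode. Default 2.
#' @param replicates Gamete libraries per (population, sex) group.
#'   Default 3.
#' @param n_genes Genes per species. Default 1200.
#' @param n_sco 1:1 orthologues (<= n_genes). Default 400.
#' @param frac_female_biased,frac_male_biased Proportions of planted
#'   sex-biased genes. Defaults 0.004 each.
#' @param frac_convergent Proportion of SCOs with a planted asexuality
#'   shift. Default 0.067.
#' @param bias_log2fc,convergent_log2fc Planted effect sizes in log2
#'   units. Defaults 2.
#' @param nb_dispersion NB dispersion alpha. Default 0.2.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene relative expression. Defaults 3 and 1.5.
#' @param library_size_mean Mean library size; per-library sizes are drawn
#'   log-normal with sdlog 0.2 around it. Default 5e5.
#' @param theta_sexual,theta_amazon Per-site diversity parameters per
#'   reproductive mode. Defaults 0.01 and 0.002.
#' @param poly_omega Acceptance probability of nonsynonymous background
#'   polymorphisms (purifying selection on segregating variation; 1 =
#'   neutral). Default 0.3.
#' @param hapspec_omega_factor Extra factor on `poly_omega` for
#'   haploid-specific genes (stronger haploid purifying selection).
#'   Default 0.5.
#' @param frac_haploid_specific Proportion of genes expressed only in
#'   gametophytes. Default 0.1.
#' @param n_planted_amazon_missense Amazon-fixed missense candidates per
#'   species, of which exactly 1 lies on a shared SCO. Default 16.
#' @param cds_codon_range Range of sense-codon counts per CDS.
#'   Default c(80, 400).
#' @param sco_divergence Per-site substitution attempt rate between the
#'   two species' SCO CDS (pairs are emitted aligned). Default 0.2.
#' @param sco_omega_accept Acceptance probability of nonsynonymous
#'   substitution attempts (purifying selection; synonymous attempts are
#'   always accepted). Default 0.25.
#' @param depth_mean Mean sequencing depth per call (floored at 10).
#'   Default 20.
#' @param species Names of the two species.
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(populations_per_mode = 2, replicates = 3,
                              n_genes = 1200, n_sco = 400,
                              frac_female_biased = 0.004,
                              frac_male_biased = 0.004,
                              frac_convergent = 0.067,
                              bias_log2fc = 2, convergent_log2fc = 2,
                              nb_dispersion = 0.2,
                              baseline_log_mean = 3, baseline_log_sd = 1.5,
                              library_size_mean = 5e5,
                              theta_sexual = 0.01, theta_amazon = 0.002,
                              poly_omega = 0.3,
                              hapspec_omega_factor = 0.5,
                              frac_haploid_specific = 0.1,
                              n_planted_amazon_missense = 16,
                              cds_codon_range = c(80, 400),
                              sco_divergence = 0.2,
                              sco_omega_accept = 0.25,
                              depth_mean = 20,
                              species = c("species1", "species2"),
                              seed = 1) {
  cfg <- list(n_species = 2, populations_per_mode = populations_per_mode,
              replicates = replicates, n_genes = n_genes, n_sco = n_sco,
              frac_female_biased = frac_female_biased,
              frac_male_biased = frac_male_biased,
              frac_convergent = frac_convergent,
              bias_log2fc = bias_log2fc,
              convergent_log2fc = convergent_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              library_size_mean = library_size_mean,
              theta_sexual = theta_sexual, theta_amazon = theta_amazon,
              poly_omega = poly_omega,
              hapspec_omega_factor = hapspec_omega_factor,
              frac_haploid_specific = frac_haploid_specific,
              n_planted_amazon_missense = n_planted_amazon_missense,
              cds_codon_range = cds_codon_range,
              sco_divergence = sco_divergence,
              sco_omega_accept = sco_omega_accept,
              depth_mean = depth_mean,
              species = species, seed = seed)
  for (f in c("frac_female_biased", "frac_male_biased", "frac_convergent",
              "frac_haploid_specific"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      .stopf("configuration error: %s must lie in [0, 1]", f)
  if (cfg$frac_female_biased + cfg$frac_male_biased > 1)
    .stopf("configuration error: frac_female_biased + frac_male_biased > 1")
  if (cfg$nb_dispersion < 0)
    .stopf("configuration error: nb_dispersion must be >= 0")
  if (cfg$replicates < 1)
    .stopf("configuration error: replicates must be >= 1")
  if (cfg$populations_per_mode < 1)
    .stopf("configuration error: populations_per_mode must be >= 1")
  if (cfg$n_sco > cfg$n_genes)
    .stopf("configuration error: n_sco must not exceed n_genes")
  if (cfg$theta_sexual < 0 || cfg$theta_amazon < 0)
    .stopf("configuration error: theta parameters must be >= 0")
  if (cfg$poly_omega < 0 || cfg$poly_omega > 1 ||
      cfg$hapspec_omega_factor < 0 || cfg$hapspec_omega_factor > 1)
    .stopf("configuration error: polymorphism selection parameters must lie in [0, 1]")
  if (length(cfg$species) != 2)
    .stopf("configuration error: species must name exactly 2 species")
  if (cfg$sco_divergence < 0 || cfg$sco_divergence > 1 ||
      cfg$sco_omega_accept < 0 || cfg$sco_omega_accept > 1)
    .stopf("configuration error: sco divergence parameters must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Sample sheet for the emulated study design
#'
#' Deterministic given the configuration: per species, each sexual
#' population contributes `replicates` female and `replicates` male gamete
#' libraries; each Amazon population contributes `replicates` female gamete
#' libraries; plus 3 gametophyte thallus libraries per sex and 3 sporophyte
#' thallus libraries (population "genlib", sporophytes with sex NA).
#'
#' @param config A [simulation_config()].
#' @return Sample sheet data.frame (see [read_sample_sheet()]).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  add <- function(sp, pop, sex, mode, generation, tissue, r) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sprintf("%s_%s_%s_r%d", sp, pop,
                          if (is.na(sex)) "sp" else substr(sex, 1, 1), r),
      species = sp, population = pop, sex = sex, mode = mode,
      generation = generation, tissue = tissue, replicate = r,
      stringsAsFactors = FALSE)
  }
  for (sp in config$species) {
    for (j in seq_len(config$populations_per_mode)) {
      pop <- sprintf("sex%d", j)
      for (sex in c("female", "male"))
        for (r in seq_len(config$replicates))
          add(sp, pop, sex, "sexual", "gametophyte", "gamete", r)
    }
    for (j in seq_len(config$populations_per_mode)) {
      pop <- sprintf("amz%d", j)
      for (r in seq_len(config$replicates))
        add(sp, pop, "female", "amazon", "gametophyte", "gamete", r)
    }
    for (sex in c("female", "male"))
      for (r in 1:3)
        add(sp, "genlib", sex, "sexual", "gametophyte", "thallus", r)
    for (r in 1:3)
      add(sp, "genlib", NA_character_, "sexual", "sporophyte", "thallus", r)
  }
  design <- do.call(rbind, rows)
  validate_sample_sheet(design)
  design
}

.gene_ids <- function(config, sp_index) {
  sprintf("%s_g%04d", config$species[sp_index], seq_len(config$n_genes))
}

#' Orthologue map of the simulated species pair
#'
#' The first `n_sco` genes of each species are paired as single-copy
#' orthologues.
#'
#' @param config A [simulation_config()].
#' @return Orthologue map data.frame.
#' @export
generate_ortho_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(sco_id = sprintf("OG%05d", seq_len(config$n_sco)),
             gene_id_species1 = .gene_ids(config, 1)[seq_len(config$n_sco)],
             gene_id_species2 = .gene_ids(config, 2)[seq_len(config$n_sco)],
             stringsAsFactors = FALSE)
}

# evolve a CDS: per-site substitution attempts, synonymous ones always
# accepted, nonsynonymous accepted with prob omega_accept, never creating
# an internal stop; the terminal stop codon is left untouched
.mutate_cds <- function(cds, rate, omega_accept) {
  bases <- c("A", "C", "G", "T")
  n_sense <- nchar(cds) - 3
  hit <- which(runif(n_sense) < rate)
  for (i in hit) {
    codon_n <- (i - 1) %/% 3 + 1
    pos_in <- (i - 1) %% 3 + 1
    codon <- substr(cds, 3 * codon_n - 2, 3 * codon_n)
    b <- sample(setdiff(bases, substr(codon, pos_in, pos_in)), 1)
    mut <- codon
    substr(mut, pos_in, pos_in) <- b
    if (.is_stop_codon(mut)) next
    syn <- .translate_codon(mut) == .translate_codon(codon)
    if (!syn && runif(1) > omega_accept) next
    substr(cds, i, i) <- b
  }
  cds
}

#' Simulate gene models (contigs, exons, strand, random-sense-codon CDS)
#'
#' Each gene sits on its own contig behind a short flank; CDS are uniform
#' random sense codons with a terminal stop codon appended; ~30% of genes
#' are split into two exons and ~20% lie on the minus strand. SCO pairs
#' are emitted aligned: the species-2 CDS is derived from the species-1
#' CDS by per-site substitutions under purifying selection
#' (`sco_divergence`, `sco_omega_accept`).
#'
#' @param config A [simulation_config()].
#' @return Named list (per species) of [gene_annotation()] objects.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2)
  sense <- .sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  sp1_cds <- NULL
  for (si in 1:2) {
    sp <- config$species[si]
    ids <- .gene_ids(config, si)
    genes <- list(); exons <- list(); cds <- character(0)
    for (gi in seq_along(ids)) {
      g <- ids[gi]
      if (si == 2 && gi <= config$n_sco) {
        s <- .mutate_cds(sp1_cds[[gi]], config$sco_divergence,
                         config$sco_omega_accept)
      } else {
        nc <- sample(config$cds_codon_range[1]:config$cds_codon_range[2], 1)
        s <- paste(c(sample(sense, nc, replace = TRUE), sample(stops, 1)),
                   collapse = "")
      }
      len <- nchar(s)
      contig <- sprintf("ctg_%s", g)
      strand <- sample(c("+", "-"), 1, prob = c(0.8, 0.2))
      flank <- 30
      if (runif(1) < 0.3 && len > 6) {
        cut <- sample(seq_len(len - 1), 1)
        ex <- data.frame(gene_id = g,
                         start = c(flank + 1, flank + cut + 51),
                         end = c(flank + cut, flank + len + 50))
      } else {
        ex <- data.frame(gene_id = g, start = flank + 1, end = flank + len)
      }
      genes[[g]] <- data.frame(gene_id = g, contig = contig,
                               strand = strand, stringsAsFactors = FALSE)
      exons[[g]] <- ex
      cds[[g]] <- s
    }
    out[[sp]] <- gene_annotation(do.call(rbind, genes),
                                 do.call(rbind, exons), cds)
    if (si == 1) sp1_cds <- unname(cds)
  }
  out
}

# planted-label draws shared by the counts and variants simulators; own
# RNG substream so either op is reproducible on its own
.sim_labels <- function(config) {
  set.seed(config$seed + 4)
  n <- config$n_genes
  n_conv <- round(config$frac_convergent * config$n_sco)
  conv_sco <- sort(sample(config$n_sco, n_conv))
  conv_dir <- sample(c(1, -1), n_conv, replace = TRUE)
  out <- list(conv_sco = conv_sco, conv_dir = conv_dir)
  for (si in 1:2) {
    n_f <- round(config$frac_female_biased * n)
    n_m <- round(config$frac_male_biased * n)
    pool <- setdiff(seq_len(n), conv_sco)
    biased <- sample(pool, n_f + n_m)
    fb <- biased[seq_len(n_f)]
    mb <- setdiff(biased, fb)
    hap <- sample(n, round(config$frac_haploid_specific * n))
    out[[config$species[si]]] <- list(fb = fb, mb = mb, hap = hap)
  }
  out
}

#' Simulate count matrices with planted effects
#'
#' Counts are NB(mean = library_size * q, var = mu + alpha mu^2) where
#' log2 q adds `bias_log2fc` for planted sex-biased genes in the favoured
#' sex (sexual populations only) and +/- `convergent_log2fc` for planted
#' convergent SCOs in all Amazon samples of both species (same sign in
#' both). SCO pairs share their baseline mean across species. Haploid-
#' specific genes have zero mean in sporophyte libraries. Gene lengths are
#' taken from the CDS models.
#'
#' @param design Sample sheet from [generate_design()].
#' @param config A [simulation_config()].
#' @param annotation Optional list from [simulate_annotation()]
#'   (regenerated from the config when missing).
#' @return List: `counts` (named list of [count_matrix()] per species),
#'   `truth` (list with `genes` and `scos` truth-label data.frames).
#' @export
simulate_counts <- function(design, config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sample_sheet(design)
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  labels <- .sim_labels(config)
  set.seed(config$seed + 1)
  n <- config$n_genes
  ortho <- generate_ortho_map(config)
  base1 <- rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  base2 <- c(base1[seq_len(config$n_sco)],
             rnorm(n - config$n_sco, config$baseline_log_mean,
                   config$baseline_log_sd))
  conv_sco <- labels$conv_sco
  conv_dir <- labels$conv_dir
  n_conv <- length(conv_sco)
  sco_truth <- data.frame(sco_id = ortho$sco_id, convergent = FALSE,
                          direction = NA_character_,
                          stringsAsFactors = FALSE)
  sco_truth$convergent[conv_sco] <- TRUE
  sco_truth$direction[conv_sco] <- ifelse(conv_dir > 0, "up_in_amazon",
                                          "down_in_amazon")
  counts <- list()
  gene_truth <- list()
  for (si in 1:2) {
    sp <- config$species[si]
    ids <- .gene_ids(config, si)
    base <- if (si == 1) base1 else base2
    # planted bias is kept off the convergent SCO genes so truth stays clean
    fb <- labels[[sp]]$fb
    mb <- labels[[sp]]$mb
    hap <- labels[[sp]]$hap
    sub <- design[design$species == sp, , drop = FALSE]
    lsize <- rlnorm(nrow(sub), log(config$library_size_mean), 0.2)
    m <- matrix(0L, n, nrow(sub), dimnames = list(ids, sub$sample_id))
    conv_shift <- numeric(n)
    conv_shift[conv_sco] <- conv_dir * config$convergent_log2fc * log(2)
    for (k in seq_len(nrow(sub))) {
      s <- sub[k, ]
      lq <- base
      if (s$mode == "sexual" && s$tissue == "gamete" && !is.na(s$sex)) {
        if (s$sex == "female") lq[fb] <- lq[fb] + config$bias_log2fc * log(2)
        if (s$sex == "male") lq[mb] <- lq[mb] + config$bias_log2fc * log(2)
      }
      if (s$mode == "amazon") lq <- lq + conv_shift
      q <- exp(lq)
      if (s$generation == "sporophyte") q[hap] <- 0
      mu <- lsize[k] * q / sum(q)
      m[, k] <- as.integer(if (config$nb_dispersion > 0)
        rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
        else rpois(n, mu))
    }
    lens <- nchar(annotation[[sp]]$cds[ids])
    counts[[sp]] <- count_matrix(m, lens)
    bias_class <- rep("unbiased", n)
    bias_class[fb] <- "female_biased"
    bias_class[mb] <- "male_biased"
    gene_truth[[sp]] <- data.frame(species = sp, gene_id = ids,
                                   bias_class_planted = bias_class,
                                   haploid_specific = seq_len(n) %in% hap,
                                   stringsAsFactors = FALSE)
  }
  list(counts = counts,
       truth = list(genes = do.call(rbind, gene_truth), scos = sco_truth))
}

# genomic coordinate + genomic ref base of a CDS index
.genomic_pos <- function(ann, gene_id, cds_idx) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  e <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  lens <- e$end - e$start + 1
  if (g$strand == "+") {
    cum <- cumsum(lens)
    hit <- which(cds_idx <= cum)[1]
    before <- if (hit > 1) cum[hit - 1] else 0
    pos <- e$start[hit] + (cds_idx - before - 1)
  } else {
    cum <- cumsum(rev(lens))  # from the last exon downwards
    hit_rev <- which(cds_idx <= cum)[1]
    hit <- nrow(e) - hit_rev + 1
    before <- if (hit_rev > 1) cum[hit_rev - 1] else 0
    pos <- e$end[hit] - (cds_idx - before - 1)
  }
  base <- substr(ann$cds[[gene_id]], cds_idx, cds_idx)
  if (g$strand == "-") base <- .complement(base)
  list(contig = g$contig, pos = pos, ref = base, strand = g$strand)
}

#' Simulate haploid variant tables with planted Amazon candidates
#'
#' Background segregating sites are placed per population with per-site
#' probability equal to the theta of its reproductive mode; haploid alt
#' counts are uniform on 1..n-1 within the population. Per-sample depth is
#' floored at 10 reads and alt-supporting reads equal depth for alt calls.
#' `n_planted_amazon_missense` missense variants per species are fixed
#' (alt) in every Amazon sample and callable-reference in every sexual
#' sample; exactly one planted candidate per species lies on the shared
#' SCO.
#'
#' @param design Sample sheet.
#' @param annotation List from [simulate_annotation()].
#' @param config A [simulation_config()].
#' @return List: `variants` (named list of [variant_table()] per species),
#'   `truth` (data.frame of planted candidates with the shared SCO
#'   flagged).
#' @export
simulate_variants <- function(design, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sample_sheet(design)
  for (sp in config$species) {
    cds <- annotation[[sp]]$cds
    if (any(nchar(cds) %% 3 != 0))
      .stopf("annotation error: CDS length not a multiple of 3")
  }
  labels <- .sim_labels(config)
  set.seed(config$seed + 3)
  ortho <- generate_ortho_map(config)
  shared_sco_idx <- sample(config$n_sco, 1)
  bases <- c("A", "C", "G", "T")
  out_v <- list(); out_truth <- list()
  for (si in 1:2) {
    sp <- config$species[si]
    ann <- annotation[[sp]]
    ids <- .gene_ids(config, si)
    sub <- design[design$species == sp & design$generation == "gametophyte", ,
                  drop = FALSE]
    if ("tissue" %in% names(sub))
      sub <- sub[sub$tissue == "gamete", , drop = FALSE]
    samples <- sub$sample_id
    ns <- length(samples)

    # planted Amazon-fixed missense candidates
    shared_gene <- if (si == 1)
      ortho$gene_id_species1[shared_sco_idx] else
        ortho$gene_id_species2[shared_sco_idx]
    non_sco <- setdiff(ids, if (si == 1) ortho$gene_id_species1 else
      ortho$gene_id_species2)
    n_extra <- max(0, config$n_planted_amazon_missense - 1)
    planted_genes <- if (config$n_planted_amazon_missense == 0)
      character(0) else
        c(shared_gene, if (n_extra > 0) sample(non_sco, n_extra))
    planted <- list()
    for (g in planted_genes) {
      cds <- ann$cds[[g]]
      n_sense <- nchar(cds) / 3 - 1
      repeat {
        codon_i <- sample(n_sense, 1)
        pos_in <- sample(3, 1)
        idx <- 3 * (codon_i - 1) + pos_in
        codon <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
        alts <- setdiff(bases, substr(codon, pos_in, pos_in))
        ok <- vapply(alts, function(b) {
          mut <- codon
          substr(mut, pos_in, pos_in) <- b
          aa <- .translate_codon(mut)
          aa != "*" && aa != .translate_codon(codon)
        }, logical(1))
        if (any(ok)) {
          alt_cds <- sample(rep(alts[ok], 2), 1)
          break
        }
      }
      gp <- .genomic_pos(ann, g, idx)
      alt_gen <- if (gp$strand == "-") .complement(alt_cds) else alt_cds
      planted[[g]] <- data.frame(gene_id = g, cds_idx = idx,
                                 contig = gp$contig, pos = gp$pos,
                                 ref = gp$ref, alt = alt_gen,
                                 stringsAsFactors = FALSE)
    }
    planted <- if (length(planted) > 0) do.call(rbind, planted) else NULL

    # background segregating sites per population; nonsynonymous proposals
    # are thinned by purifying selection (poly_omega, and additionally
    # hapspec_omega_factor on haploid-specific genes)
    hap_ids <- ids[labels[[sp]]$hap]
    ev <- list()
    for (pop in unique(sub$population)) {
      psamp <- sub$sample_id[sub$population == pop]
      np <- length(psamp)
      if (np < 2) next
      mode <- sub$mode[sub$population == pop][1]
      theta <- if (mode == "amazon") config$theta_amazon else
        config$theta_sexual
      if (theta <= 0) next
      for (g in ids) {
        cds_g <- ann$cds[[g]]
        n_sense_nt <- nchar(cds_g) - 3
        nseg <- rbinom(1, n_sense_nt, theta)
        if (nseg == 0) next
        cds_pos <- sample(n_sense_nt, nseg)
        # keep planted candidate positions clean
        if (!is.null(planted) && g %in% planted$gene_id)
          cds_pos <- setdiff(cds_pos, planted$cds_idx[planted$gene_id == g])
        for (ix in cds_pos) {
          codon_n <- (ix - 1) %/% 3 + 1
          pos_in <- (ix - 1) %% 3 + 1
          codon <- substr(cds_g, 3 * codon_n - 2, 3 * codon_n)
          alt_cds <- sample(setdiff(bases, substr(codon, pos_in, pos_in)), 1)
          mut <- codon
          substr(mut, pos_in, pos_in) <- alt_cds
          syn <- !.is_stop_codon(mut) &&
            .translate_codon(mut) == .translate_codon(codon)
          if (!syn) {
            acc <- config$poly_omega *
              (if (g %in% hap_ids) config$hapspec_omega_factor else 1)
            if (runif(1) > acc) next
          }
          k <- if (np == 2) 1 else sample(np - 1, 1)
          ev[[length(ev) + 1]] <- list(gene = g, idx = ix, alt = alt_cds,
                                       carriers = sample(psamp, k))
        }
      }
    }

    # merge events into sites
    site_key <- vapply(ev, function(e) sprintf("%s:%d", e$gene, e$idx),
                       character(1))
    keys <- unique(site_key)
    n_total <- length(keys) + NROW(planted)
    gt <- matrix(0L, n_total, ns, dimnames = list(NULL, samples))
    sites <- vector("list", n_total)
    row <- 0
    for (kk in keys) {
      row <- row + 1
      first <- ev[[which(site_key == kk)[1]]]
      gp <- .genomic_pos(ann, first$gene, first$idx)
      alt <- if (gp$strand == "-") .complement(first$alt) else first$alt
      sites[[row]] <- data.frame(contig = gp$contig, pos = gp$pos,
                                 ref = gp$ref, alt = alt,
                                 qual = round(runif(1, 30, 60), 1),
                                 stringsAsFactors = FALSE)
      for (e in ev[site_key == kk]) gt[row, e$carriers] <- 1L
    }
    if (NROW(planted) > 0) {
      amz <- sub$sample_id[sub$mode == "amazon"]
      for (i in seq_len(nrow(planted))) {
        row <- row + 1
        sites[[row]] <- data.frame(contig = planted$contig[i],
                                   pos = planted$pos[i],
                                   ref = planted$ref[i],
                                   alt = planted$alt[i],
                                   qual = round(runif(1, 40, 60), 1),
                                   stringsAsFactors = FALSE)
        gt[row, amz] <- 1L
      }
    }
    if (n_total == 0) {
      empty <- matrix(integer(0), 0, ns, dimnames = list(NULL, samples))
      out_v[[sp]] <- variant_table(
        data.frame(contig = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   qual = numeric(0)), empty, empty, empty)
      next
    }
    sites <- do.call(rbind, sites)
    dp <- matrix(pmax(10L, rpois(n_total * ns, config$depth_mean)),
                 n_total, ns, dimnames = list(NULL, samples))
    ar <- ifelse(gt == 1L, dp, 0L)
    ord <- order(sites$contig, sites$pos)
    out_v[[sp]] <- variant_table(sites[ord, , drop = FALSE],
                                 gt[ord, , drop = FALSE],
                                 dp[ord, , drop = FALSE],
                                 ar[ord, , drop = FALSE])
    if (NROW(planted) > 0) {
      sco <- ortho$sco_id[match(planted$gene_id,
                                if (si == 1) ortho$gene_id_species1 else
                                  ortho$gene_id_species2)]
      out_truth[[sp]] <- data.frame(species = sp, planted,
                                    sco_id = sco,
                                    shared = !is.na(sco) &
                                      sco == ortho$sco_id[shared_sco_idx],
                                    stringsAsFactors = FALSE)
    }
  }
  list(variants = out_v,
       truth = if (length(out_truth) > 0) do.call(rbind, out_truth) else
         NULL)
}

#' Simulate a complete fixture bundle
#'
#' Runs [generate_design()], [simulate_annotation()], [simulate_counts()],
#' [generate_ortho_map()] and [simulate_variants()] under the config seed.
#'
#' @param config A [simulation_config()].
#' @return List: config, design, ortho, annotation, counts, variants,
#'   truth (genes, scos, candidates).
#' @export
simulate_bundle <- function(config) {
  design <- generate_design(config)
  annotation <- simulate_annotation(config)
  cnt <- simulate_counts(design, config, annotation)
  var <- simulate_variants(design, annotation, config)
  list(config = config, design = design,
       ortho = generate_ortho_map(config), annotation = annotation,
       counts = cnt$counts, variants = var$variants,
       truth = list(genes = cnt$truth$genes, scos = cnt$truth$scos,
                    candidates = var$truth))
}

#' Write a fixture bundle to disk with a checksum manifest
#'
#' Writes counts TSVs, the sample sheet, the orthologue map, CDS FASTA and
#' GFF-lite annotation, VCFs and the truth-label TSVs; the manifest lists
#' every file with its MD5 checksum. Truth labels are written but never
#' read by any analysis function.
#'
#' @param bundle From [simulate_bundle()].
#' @param dir_path Output directory (created if needed).
#' @return data.frame manifest (file, md5), also written as manifest.tsv.
#' @export
write_fixture_bundle <- function(bundle, dir_path) {
  if (!dir.exists(dir_path))
    if (!dir.create(dir_path, recursive = TRUE))
      .stopf("cannot create directory %s", dir_path)
  files <- character(0)
  wf <- function(fn) {
    files <<- c(files, fn)
    file.path(dir_path, fn)
  }
  write_sample_sheet(bundle$design, wf("samples.tsv"))
  write_ortho_map(bundle$ortho, wf("ortho_map.tsv"))
  for (sp in names(bundle$counts))
    write_counts(bundle$counts[[sp]], wf(sprintf("counts_%s.tsv", sp)))
  for (sp in names(bundle$annotation))
    write_annotation(bundle$annotation[[sp]],
                     wf(sprintf("annotation_%s.gff", sp)),
                     wf(sprintf("cds_%s.fasta", sp)))
  for (sp in names(bundle$variants))
    write_vcf(bundle$variants[[sp]], wf(sprintf("variants_%s.vcf", sp)))
  write.table(bundle$truth$genes, wf("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$scos, wf("truth_scos.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth$candidates))
    write.table(bundle$truth$candidates, wf("truth_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  md5 <- tools::md5sum(file.path(dir_path, files))
  manifest <- data.frame(file = files, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir_path, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
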