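# Amazon-candidate filter cascade: variant positions carried by every
# Amazon sample (depth >= 9, alt-supporting reads >= 7), callable-reference
# in every sexual sample, located on an exon feature; plus the
# cross-species orthologue intersection.

#' Amazon-candidate filter cascade
#'
#' A site survives when (i) every Amazon sample of the species carries the
#' alternate allele with depth >= `min_dp` and alt-supporting reads >=
#' `min_alt_reads`; (ii) every sexual sample (female and male) is callable
#' (depth >= `min_dp`) and carries the reference allele (missing calls
#' reject the site); and (iii) the position lies on an exon feature. The
#' effect (synonymous/nonsynonymous) is annotated by codon substitution.
#'
#' @param vt A [variant_table()] for one species.
#' @param design Sample sheet (restricted internally to gamete samples of
#'   `species`).
#' @param annotation A [gene_annotation()].
#' @param species Species identifier.
#' @param min_dp Minimum depth for both alt and reference calls. Default 9.
#' @param min_alt_reads Minimum alt-supporting reads in Amazons. Default 7.
#' @return A `candidate_table` data.frame (species, contig, pos, ref, alt,
#'   gene_id, effect, n_amazon, n_sexual) with an `audit` attribute giving
#'   the per-stage rejection counts (sums to the input size).
#' @export
candidate_cascade <- function(vt, design, annotation, species,
                              min_dp = 9, min_alt_reads = 7) {
  stopifnot(inherits(vt, "variant_table"))
  validate_sample_sheet(design)
  sub <- design[design$species == species &
                  design$generation == "gametophyte", , drop = FALSE]
  if ("tissue" %in% names(sub))
    sub <- sub[sub$tissue == "gamete", , drop = FALSE]
  amz <- intersect(sub$sample_id[sub$mode == "amazon"], vt$samples)
  sxl <- intersect(sub$sample_id[sub$mode == "sexual"], vt$samples)
  if (length(sxl) == 0) .stopf("no sexual samples for species %s", species)
  if (length(amz) == 0) .stopf("no amazon samples for species %s", species)
  n_in <- n_sites(vt)
  audit <- c(input = n_in, fail_amazon = 0L, fail_sexual = 0L,
             fail_exon = 0L, passed = 0L)
  rows <- list()
  if (n_in > 0) {
    gt_a <- vt$gt[, amz, drop = FALSE]
    dp_a <- vt$dp[, amz, drop = FALSE]
    ar_a <- vt$alt_reads[, amz, drop = FALSE]
    gt_s <- vt$gt[, sxl, drop = FALSE]
    dp_s <- vt$dp[, sxl, drop = FALSE]
    ok_amz <- rowSums(!is.na(gt_a) & gt_a == 1 & dp_a >= min_dp &
                        ar_a >= min_alt_reads) == length(amz)
    ok_sxl <- rowSums(!is.na(gt_s) & gt_s == 0 & dp_s >= min_dp) ==
      length(sxl)
    audit["fail_amazon"] <- sum(!ok_amz)
    audit["fail_sexual"] <- sum(ok_amz & !ok_sxl)
    for (i in which(ok_amz & ok_sxl)) {
      eff <- tryCatch(classify_effect(vt$sites[i, ], annotation),
                      error = function(e) NULL)
      if (is.null(eff)) {
        audit["fail_exon"] <- audit["fail_exon"] + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = species, contig = vt$sites$contig[i],
        pos = vt$sites$pos[i], ref = vt$sites$ref[i],
        alt = vt$sites$alt[i], gene_id = attr(eff, "gene_id"),
        effect = as.character(eff), n_amazon = length(amz),
        n_sexual = length(sxl), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = character(0), contig = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               gene_id = character(0), effect = character(0),
               n_amazon = integer(0), n_sexual = integer(0))
  audit["passed"] <- nrow(out)
  attr(out, "audit") <- audit
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Orthologues carrying Amazon candidates in both species
#'
#' @param cands_sp1,cands_sp2 `candidate_table`s from [candidate_cascade()].
#' @param ortho Orthologue map.
#' @param effect_filter Candidate effect class required in both species.
#'   Default "nonsynonymous" (missense focus); NULL disables the filter.
#' @return data.frame: sco_id, gene ids and candidate positions per species
#'   (semicolon-separated; positions need not be homologous).
#' @export
cross_species_candidates <- function(cands_sp1, cands_sp2, ortho,
                                     effect_filter = "nonsynonymous") {
  validate_ortho_map(ortho)
  pick <- function(cands) {
    if (!is.null(effect_filter))
      cands <- cands[cands$effect == effect_filter, , drop = FALSE]
    cands
  }
  c1 <- pick(cands_sp1); c2 <- pick(cands_sp2)
  sco1 <- ortho$sco_id[match(c1$gene_id, ortho$gene_id_species1)]
  sco2 <- ortho$sco_id[match(c2$gene_id, ortho$gene_id_species2)]
  shared <- intersect(sco1[!is.na(sco1)], sco2[!is.na(sco2)])
  if (length(shared) == 0)
    return(data.frame(sco_id = character(0), gene_id_species1 = character(0),
                      gene_id_species2 = character(0),
                      pos_species1 = character(0),
                      pos_species2 = character(0)))
  do.call(rbind, lapply(shared, function(sc) {
    g1 <- ortho$gene_id_species1[ortho$sco_id == sc]
    g2 <- ortho$gene_id_species2[ortho$sco_id == sc]
    p1 <- c1[c1$gene_id == g1, , drop = FALSE]
    p2 <- c2[c2$gene_id == g2, , drop = FALSE]
    data.frame(sco_id = sc, gene_id_species1 = g1, gene_id_species2 = g2,
               pos_species1 = paste(sprintf("%s:%d", p1$contig, p1$pos),
                                    collapse = ";"),
               pos_species2 = paste(sprintf("%s:%d", p2$contig, p2$pos),
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
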