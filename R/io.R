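# TSV / FASTA / GFF-lite / VCF readers and writers. All tabular files are
# tab-delimited with a header row, UTF-8, '.' decimal. Coordinates in GFF
# and VCF are 1-based inclusive.

#' Read / write a sample sheet
#'
#' Columns: sample_id, species, population, sex, mode (sexual/amazon),
#' generation (gametophyte/sporophyte), tissue (gamete/thallus), replicate.
#'
#' @param path File path.
#' @return `read_sample_sheet`: a data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param design Sample sheet data.frame.
#' @export
write_sample_sheet <- function(design, path) {
  validate_sample_sheet(design)
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' Checks uniqueness of sample ids, the allowed factor levels, and that
#' every amazon sample is female.
#'
#' @param design Sample sheet data.frame.
#' @return The design, invisibly.
#' @export
validate_sample_sheet <- function(design) {
  .assert_cols(design, c("sample_id", "species", "population", "sex",
                         "mode", "generation", "replicate"),
               "sample sheet")
  if (anyDuplicated(design$sample_id))
    .stopf("duplicate sample_id in sample sheet")
  if (!all(design$mode %in% c("sexual", "amazon")))
    .stopf("mode must be 'sexual' or 'amazon'")
  if (!all(design$generation %in% c("gametophyte", "sporophyte")))
    .stopf("generation must be 'gametophyte' or 'sporophyte'")
  if (!all(design$sex %in% c("female", "male") | is.na(design$sex)))
    .stopf("sex must be 'female', 'male' or NA")
  amz <- design$mode == "amazon"
  if (any(amz & (is.na(design$sex) | design$sex != "female")))
    .stopf("every amazon sample must have sex = 'female'")
  invisible(design)
}

#' Read / write a count matrix TSV
#'
#' Layout: first columns `gene_id` and `length_bp`, then one column per
#' sample.
#'
#' @param path File path.
#' @return `read_counts`: a [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .assert_cols(df, c("gene_id", "length_bp"), "counts file")
  m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                    drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(m, df$length_bp)
}

#' @rdname read_counts
#' @param cm A [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts),
                   length_bp = unname(cm$length_bp),
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a 1:1 orthologue map
#'
#' Columns: sco_id, gene_id_species1, gene_id_species2. The map must be
#' bijective per species.
#'
#' @param path File path.
#' @return `read_ortho_map`: a data.frame.
#' @export
read_ortho_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_ortho_map(df)
  df
}

#' @rdname read_ortho_map
#' @param ortho Orthologue map data.frame.
#' @export
write_ortho_map <- function(ortho, path) {
  validate_ortho_map(ortho)
  write.table(ortho, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ortho_map
#' @export
validate_ortho_map <- function(ortho) {
  .assert_cols(ortho, c("sco_id", "gene_id_species1", "gene_id_species2"),
               "orthologue map")
  if (anyDuplicated(ortho$sco_id) || anyDuplicated(ortho$gene_id_species1) ||
      anyDuplicated(ortho$gene_id_species2))
    .stopf("orthologue map must be 1:1 (no duplicated sco or gene ids)")
  invisible(ortho)
}

#' Gene annotation (exon models + in-frame CDS)
#'
#' @param genes data.frame with columns gene_id, contig, strand (+/-).
#' @param exons data.frame with columns gene_id, start, end (1-based
#'   inclusive, non-overlapping, sorted by genomic position per gene).
#' @param cds Named character vector: gene_id -> CDS sequence (5'->3' on
#'   the coding strand, in frame; a single terminal stop codon is allowed).
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, cds) {
  .assert_cols(genes, c("gene_id", "contig", "strand"), "genes table")
  .assert_cols(exons, c("gene_id", "start", "end"), "exons table")
  if (!all(genes$strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  cds <- toupper(cds)
  for (g in genes$gene_id) {
    s <- cds[[g]]
    if (is.null(s) || is.na(s)) .stopf("missing CDS for gene %s", g)
    if (nchar(s) %% 3 != 0)
      .stopf("CDS length of gene %s is not a multiple of 3", g)
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    internal <- cods[-length(cods)]
    ok <- internal[internal %in% names(.codon_aa_table())]
    if (any(.is_stop_codon(ok)))
      .stopf("internal stop codon in CDS of gene %s", g)
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    if (nrow(ex) == 0) .stopf("no exons for gene %s", g)
    if (is.unsorted(ex$start)) .stopf("exons of gene %s are not sorted", g)
    if (any(ex$end < ex$start)) .stopf("bad exon interval in gene %s", g)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      .stopf("overlapping exons in gene %s", g)
    if (sum(ex$end - ex$start + 1) != nchar(s))
      .stopf("exon span of gene %s does not match CDS length", g)
  }
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d contigs\n",
              nrow(x$genes), length(unique(x$genes$contig))))
  invisible(x)
}

#' Write / read annotation as GFF-lite plus a CDS FASTA
#'
#' GFF-lite: 9 tab-separated columns (seqid, source, type, start, end,
#' score, strand, phase, attributes) with `gene` and `CDS` rows; CDS rows
#' carry `Parent=<gene_id>`.
#'
#' @param annotation A [gene_annotation()].
#' @param gff_path,fasta_path Output paths.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  rows <- list()
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, ,
                           drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      seqid = g$contig, source = "amazonswitch", type = "gene",
      start = min(ex$start), end = max(ex$end), score = ".",
      strand = g$strand, phase = ".",
      attributes = sprintf("ID=%s", g$gene_id))
    # phase: number of bases to remove to reach the next codon start
    lens <- ex$end - ex$start + 1
    ord <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    off <- cumsum(c(0, lens[ord]))[seq_len(nrow(ex))]
    phase <- (3 - off %% 3) %% 3
    for (j in seq_len(nrow(ex))) {
      k <- ord[j]
      rows[[length(rows) + 1]] <- data.frame(
        seqid = g$contig, source = "amazonswitch", type = "CDS",
        start = ex$start[k], end = ex$end[k], score = ".",
        strand = g$strand, phase = phase[j],
        attributes = sprintf("ID=%s.cds%d;Parent=%s", g$gene_id, j,
                             g$gene_id))
    }
  }
  gff <- do.call(rbind, rows)
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  seqinr::write.fasta(lapply(annotation$cds,
                             function(s) strsplit(s, "")[[1]]),
                      names = names(annotation$cds), file.out = fasta_path,
                      nbchar = 60)
  invisible(gff_path)
}

#' @rdname write_annotation
#' @return `read_annotation`: a [gene_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path) {
  gff <- read.delim(gff_path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
  att_field <- function(att, key) {
    m <- regmatches(att, regexpr(sprintf("%s=[^;]+", key), att))
    sub(sprintf("^%s=", key), "", m)
  }
  grow <- gff[gff$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = att_field(grow$attributes, "ID"),
                      contig = grow$seqid, strand = grow$strand,
                      stringsAsFactors = FALSE)
  crow <- gff[gff$type == "CDS", , drop = FALSE]
  exons <- data.frame(gene_id = att_field(crow$attributes, "Parent"),
                      start = crow$start, end = crow$end,
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  fa <- seqinr::read.fasta(fasta_path, as.string = TRUE, forceDNAtolower = FALSE)
  cds <- setNames(toupper(vapply(fa, as.character, character(1))), names(fa))
  gene_annotation(genes, exons, cds)
}

#' Haploid per-sample variant table
#'
#' @param sites data.frame with columns contig, pos (1-based), ref, alt
#'   (single bases, alt != ref), qual (phred site quality).
#' @param gt Integer matrix sites x samples with haploid genotypes 0 (ref),
#'   1 (alt) or NA (missing); colnames are sample ids.
#' @param dp,alt_reads Integer matrices of read depth and alt-supporting
#'   reads, same shape as `gt`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp, alt_reads) {
  .assert_cols(sites, c("contig", "pos", "ref", "alt", "qual"),
               "variant sites")
  if (any(sites$ref == sites$alt)) .stopf("alt must differ from ref")
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  gt <- as.matrix(gt); dp <- as.matrix(dp); alt_reads <- as.matrix(alt_reads)
  if (nrow(gt) != nrow(sites) || !all(dim(dp) == dim(gt)) ||
      !all(dim(alt_reads) == dim(gt)))
    .stopf("gt/dp/alt_reads must have one row per site and equal dims")
  if (is.null(colnames(gt))) .stopf("gt must have sample ids as colnames")
  if (any(alt_reads > dp, na.rm = TRUE))
    .stopf("alt_reads cannot exceed depth")
  structure(list(sites = sites, gt = gt, dp = dp, alt_reads = alt_reads,
                 samples = colnames(gt)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Number of variant sites
#' @param vt A [variant_table()].
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' Write a variant table as VCF 4.2
#'
#' Haploid GT plus per-sample DP and AD (ref,alt read counts) and site QUAL.
#'
#' @param vt A [variant_table()].
#' @param path Output path (plain text).
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=amazonswitch",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")), con)
  if (n_sites(vt) > 0) {
    cells <- matrix("", n_sites(vt), length(vt$samples))
    for (j in seq_along(vt$samples)) {
      g <- vt$gt[, j]
      gs <- ifelse(is.na(g), ".", as.character(g))
      ref_reads <- vt$dp[, j] - vt$alt_reads[, j]
      cells[, j] <- sprintf("%s:%d:%d,%d", gs, vt$dp[, j], ref_reads,
                            vt$alt_reads[, j])
    }
    lines <- paste(vt$sites$contig, vt$sites$pos, ".", vt$sites$ref,
                   vt$sites$alt, vt$sites$qual, "PASS", ".", "GT:DP:AD",
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  close(con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses vcfR for parsing; expects haploid GT and per-sample DP and AD.
#' Multi-allelic records are split into biallelic rows.
#'
#' @param path VCF path.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    empty <- matrix(integer(0), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(variant_table(data.frame(contig = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    qual = numeric(0)),
                         empty, empty, empty))
  }
  gt_raw <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  out_sites <- list(); out_gt <- list(); out_dp <- list(); out_ad <- list()
  for (i in seq_len(nrow(fix))) {
    ad_i <- strsplit(ad[i, ], ",", fixed = TRUE)
    for (k in seq_along(alts[[i]])) {
      g <- gt_raw[i, ]
      gk <- ifelse(is.na(g) | g == ".", NA_integer_,
                   ifelse(g == as.character(k), 1L,
                          ifelse(g == "0", 0L, NA_integer_)))
      altk <- vapply(ad_i, function(x) {
        if (length(x) >= k + 1) as.integer(x[k + 1]) else NA_integer_
      }, integer(1))
      out_sites[[length(out_sites) + 1]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[[i]][k],
        qual = as.numeric(fix$QUAL[i]), stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1]] <- gk
      out_dp[[length(out_dp) + 1]] <- as.integer(dp[i, ])
      out_ad[[length(out_ad) + 1]] <- altk
    }
  }
  samples <- colnames(gt_raw)
  mk <- function(l) {
    m <- do.call(rbind, l)
    colnames(m) <- samples
    m
  }
  variant_table(do.call(rbind, out_sites), mk(out_gt), mk(out_dp), mk(out_ad))
}
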