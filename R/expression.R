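#' Count matrix with gene lengths
#'
#' Container for gene-level read counts plus the per-gene (effective)
#' transcript length used for TPM computation.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param length_bp Positive integer vector of gene lengths in bp, one per
#'   row of `counts` (recycled names are taken from `counts` if unnamed).
#' @return An object of class `count_matrix` with elements `counts` and
#'   `length_bp`.
#' @export
count_matrix <- function(counts, length_bp) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) .stopf("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) .stopf("counts must have sample ids as colnames")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (length(length_bp) != nrow(counts))
    .stopf("length_bp must have one entry per gene (%d != %d)",
           length(length_bp), nrow(counts))
  if (any(length_bp <= 0)) .stopf("gene lengths must be positive")
  length_bp <- setNames(as.numeric(length_bp), rownames(counts))
  structure(list(counts = counts, length_bp = length_bp),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by samples and/or genes
#'
#' @param cm A [count_matrix()].
#' @param samples,genes Character vectors of ids to keep (default: all).
#' @return A `count_matrix`.
#' @export
subset_counts <- function(cm, samples = NULL, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(counts))
    if (length(miss) > 0) .stopf("unknown gene id(s): %s", miss[1])
    counts <- counts[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(counts))
    if (length(miss) > 0) .stopf("unknown sample id(s): %s", miss[1])
    counts <- counts[, samples, drop = FALSE]
  }
  count_matrix(counts, cm$length_bp[rownames(counts)])
}

#' Transcripts-per-million from counts and gene lengths
#'
#' TPM for gene g in sample s is the length-normalised read rate
#' (count/length) scaled so each sample sums to one million:
#' `tpm_gs = (count_gs/length_g) / sum_g(count_gs/length_g) * 1e6`.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix of TPM values (same dimnames as the counts);
#'   every column sums to 1e6.
#' @export
compute_tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  zero <- colSums(cm$counts) == 0
  if (any(zero))
    .stopf("sample(s) with all-zero counts: %s",
           paste(colnames(cm$counts)[zero], collapse = ", "))
  rate <- cm$counts / cm$length_bp
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Log2(TPM + 1) expression matrix
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @return log2(tpm + 1) matrix.
#' @export
log_tpm <- function(tpm) log2(tpm + 1)

#' Expressed-gene filter (TPM threshold in a sample group)
#'
#' A gene counts as expressed in the given sample group when strictly more
#' than `threshold` TPM is observed in at least `ceiling(fraction * n)` of
#' the n group samples (default: > 0.4 TPM in at least two-thirds).
#'
#' @param tpm TPM matrix.
#' @param samples Character vector of sample ids defining the group.
#' @param threshold TPM threshold (strict inequality). Default 0.4.
#' @param fraction Required fraction of group samples. Default 2/3.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(tpm, samples, threshold = 0.4, fraction = 2 / 3) {
  if (length(samples) == 0) .stopf("empty sample set")
  miss <- setdiff(samples, colnames(tpm))
  if (length(miss) > 0) .stopf("unknown sample id(s): %s", miss[1])
  sub <- tpm[, samples, drop = FALSE]
  quota <- ceiling(fraction * length(samples))
  rownames(sub)[rowSums(sub > threshold) >= quota]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of its count to the gene's geometric mean across samples.
#' Reference genes are those with non-zero counts in every selected sample.
#'
#' @param cm A [count_matrix()] (or a plain counts matrix).
#' @param samples Optional sample ids to restrict to.
#' @return Named positive numeric vector of size factors (no rescaling).
#' @export
size_factors <- function(cm, samples = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) .stopf("no reference gene with non-zero counts in all samples")
  lc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2, function(x) exp(median(x - geo)))
}
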