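# Pairwise dN/dS between aligned orthologous CDS by the Nei-Gojobori
# counting method with Jukes-Cantor correction. Codon differences are
# resolved by averaging over all minimal substitution pathways, excluding
# pathways that pass through a stop codon.

# average synonymous/nonsynonymous difference counts between two codons
# over all orderings of the differing positions
.codon_pair_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(Sd = 0, Nd = 0))
  perms <- if (d == 1) list(pos) else {
    if (d == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
  }
  paths <- list()
  for (ord in perms) {
    cur <- ca
    steps <- c(Sd = 0, Nd = 0)
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (nxt != cb && .is_stop_codon(nxt)) {
        valid <- FALSE
        break
      }
      if (.translate_codon(nxt) == .translate_codon(cur))
        steps["Sd"] <- steps["Sd"] + 1
      else
        steps["Nd"] <- steps["Nd"] + 1
      cur <- nxt
    }
    if (valid) paths[[length(paths) + 1]] <- steps
  }
  if (length(paths) == 0) {
    # all pathways pass through a stop: fall back to unrestricted averaging
    for (ord in perms) {
      cur <- ca
      steps <- c(Sd = 0, Nd = 0)
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (.translate_codon(nxt) == .translate_codon(cur))
          steps["Sd"] <- steps["Sd"] + 1
        else
          steps["Nd"] <- steps["Nd"] + 1
        cur <- nxt
      }
      paths[[length(paths) + 1]] <- steps
    }
  }
  colMeans(do.call(rbind, paths))
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS for one aligned codon pair of sequences (NG86 counting)
#'
#' Site counts S and N are averaged over the two sequences; observed
#' synonymous/nonsynonymous differences are averaged over all minimal
#' substitution pathways per codon (stop-passing pathways excluded);
#' proportions are Jukes-Cantor corrected. A terminal stop codon pair, gap
#' codons and codons with ambiguous bases are dropped pairwise.
#'
#' @param cds_a,cds_b Aligned in-frame CDS strings of equal length.
#' @return One-row data.frame: Sd, Nd, S, N, pS, pN, dS, dN, omega, valid
#'   (TRUE iff 0 < dS < 2 and dN is finite).
#' @export
ng86_pairwise <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    .stopf("aligned CDS must have equal length")
  if (nchar(cds_a) %% 3 != 0) .stopf("CDS length is not a multiple of 3")
  n <- nchar(cds_a) / 3
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  known <- names(.codon_aa_table())
  keep <- ca %in% known & cb %in% known &
    !(.is_stop_codon(ifelse(ca %in% known, ca, "AAA")) |
        .is_stop_codon(ifelse(cb %in% known, cb, "AAA")))
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) .stopf("no scorable codons")
  tab <- .ng86_codon_table()
  S <- (sum(tab[ca]) + sum(tab[cb])) / 2
  N <- (sum(3 - tab[ca]) + sum(3 - tab[cb])) / 2
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- .codon_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  valid <- !is.na(dS) && dS > 0 && dS < 2 && !is.na(dN)
  data.frame(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
             dS = dS, dN = dN, omega = omega, valid = valid)
}

#' dN/dS for all orthologue pairs
#'
#' @param cds1,cds2 Named character vectors of CDS (gene ids of species 1
#'   and 2).
#' @param ortho Orthologue map.
#' @return `dnds_table` data.frame, one row per SCO with the
#'   [ng86_pairwise()] columns.
#' @export
dnds_orthologs <- function(cds1, cds2, ortho) {
  validate_ortho_map(ortho)
  rows <- lapply(seq_len(nrow(ortho)), function(i) {
    a <- cds1[[ortho$gene_id_species1[i]]]
    b <- cds2[[ortho$gene_id_species2[i]]]
    if (is.null(a) || is.null(b) || nchar(a) != nchar(b))
      return(cbind(data.frame(sco_id = ortho$sco_id[i]),
                   data.frame(Sd = NA, Nd = NA, S = NA, N = NA, pS = NA,
                              pN = NA, dS = NA, dN = NA, omega = NA,
                              valid = FALSE)))
    cbind(data.frame(sco_id = ortho$sco_id[i]), ng86_pairwise(a, b))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dnds_table", "data.frame")
  out
}

#' Compare dN/dS between gene classes
#'
#' Restricted to valid SCOs (0 < dS < 2). For every pair of classes, the
#' class mean omega and a two-sided Mann-Whitney p-value are reported;
#' classes with fewer than 2 valid members are flagged and not tested.
#'
#' @param dnds A `dnds_table` from [dnds_orthologs()].
#' @param classes Named character vector or factor: sco_id -> class label.
#' @return data.frame with one row per class pair: class_a, class_b,
#'   mean_a, mean_b, n_a, n_b, p_value, tested.
#' @export
rates_by_class <- function(dnds, classes) {
  v <- dnds[dnds$valid & !is.na(dnds$omega), , drop = FALSE]
  cl <- classes[v$sco_id]
  lv <- unique(stats::na.omit(as.character(cl)))
  if (length(lv) < 2) .stopf("need at least two classes with valid SCOs")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) {
    a <- v$omega[!is.na(cl) & cl == p[1]]
    b <- v$omega[!is.na(cl) & cl == p[2]]
    ok <- length(a) >= 2 && length(b) >= 2
    pv <- if (ok)
      suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
    data.frame(class_a = p[1], class_b = p[2],
               mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b),
               p_value = pv, tested = ok, stringsAsFactors = FALSE)
  }))
}
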