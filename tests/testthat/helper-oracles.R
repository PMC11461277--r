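# Independent oracles used across the suite. The genetic code comes from
# Biostrings::GENETIC_CODE so the translation source is independent of the
# package's own codon table.

oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

oracle_translate <- function(codon) unname(oracle_code[toupper(codon)])

# NG86 site counts of one codon by exhaustive single-base enumeration
oracle_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  n_syn <- 0
  for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- b
    if (oracle_translate(mut) != "*" && oracle_translate(mut) == aa)
      n_syn <- n_syn + 1
  }
  c(S = n_syn / 3, N = 3 - n_syn / 3)
}

# pathway-averaged Sd/Nd between two codons by exhaustive ordering
# enumeration (stop-passing pathways excluded; all-stop fallback keeps all)
oracle_pair_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_list(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  score <- function(ord, allow_stop) {
    cur <- ca
    sd <- nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow_stop && nxt != cb && oracle_translate(nxt) == "*")
        return(NULL)
      if (oracle_translate(nxt) == oracle_translate(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(Sd = sd, Nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(perm_list(pos), score,
                                          allow_stop = FALSE))
  if (length(paths) == 0)
    paths <- lapply(perm_list(pos), score, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

# per-site pi by O(n^2) enumeration of pairwise differences
oracle_site_pi <- function(k, n) {
  hap <- c(rep(1, k), rep(0, n - k))
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + (hap[i] != hap[j])
  diffs / choose(n, 2)
}

# tiny config used by several module tests
small_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 120, n_sco = 40, frac_female_biased = 0.05,
                   frac_male_biased = 0.05, frac_convergent = 0.1,
                   n_planted_amazon_missense = 3, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
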