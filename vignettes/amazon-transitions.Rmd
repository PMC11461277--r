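---
title: "Methods: expression and population-genomic analysis of transitions to asexuality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression and population-genomic analysis of transitions to asexuality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amazonswitch)
```

## The scientific setting

Brown algae such as *Scytosiphon* have a haplo-diplontic life cycle with
UV sex determination: sex is expressed in the haploid gametophyte
generation (U = female, V = male), and unfused female gametes can develop
parthenogenetically. Some field populations ("Amazon" populations) consist
exclusively of genetic females and reproduce only asexually. Because such
populations have arisen repeatedly and independently in related species,
they are a natural experiment for three questions:

1. Does gamete gene expression change convergently when sex is lost —
   and is it *feminized* (release from sexual antagonism) or
   *defeminized/masculinized* (decay of costly female functions)?
2. Does the loss of sex and recombination reduce the efficacy of
   purifying selection (higher nonsynonymous/synonymous diversity,
   piN/piS), or does haploid purifying selection compensate?
3. Are any coding variants perfectly associated with the asexual
   phenotype across independent transitions?

The package implements the full downstream analysis for a two-species
design: gene-level read counts with gene lengths, a sample sheet, a 1:1
orthologue map, in-frame CDS models, and haploid per-sample variant
tables in. Upstream steps (read mapping, quantification, variant calling,
orthology inference) are out of scope; the pipeline starts from counts
and VCFs.

## Expression core

TPM is computed as the length-normalised read rate scaled to one million
per sample. A gene counts as *expressed* in a sample group when strictly
more than 0.4 TPM is observed in at least `ceiling(2/3 * n)` of the `n`
group samples. Both constants are the conventional thresholds for this analysis; the strict
inequality and the ceiling are deliberate boundary choices (a gene at
exactly 0.4 TPM everywhere is not expressed, and "at least two-thirds"
is satisfiable exactly when the count is integral). The group is always
an explicit argument — there is no implicit pooling across species or
sexes.

Library-size normalisation uses median-of-ratios size factors (reference
genes are those with non-zero counts in all selected samples; factors are
returned as computed, without rescaling to unit geometric mean). The
synthetic generator deliberately jitters library sizes (log-normal,
sdlog 0.2) so this code path is exercised non-trivially.

## The negative binomial GLM engine

Sex-biased expression and convergence calls share one per-gene engine:
a log-link NB GLM with `Var(Y) = mu + alpha * mu^2`, per-sample offsets
`log(size factor)`, coefficients fitted by IRLS, and the per-gene
dispersion `alpha` maximised on its profile likelihood with the Cox–Reid
adjustment `-0.5 log det(X'WX)` (floor `1e-8`, at which the fit is
numerically Poisson; 50 iterations at relative tolerance `1e-8`). The
inner loops are compiled (Rcpp/Armadillo) because the permutation null
re-fits every orthologue hundreds of times.

Two inference routes are provided on the sex contrast:

* **Wald** (default): the coefficient over its standard error, referred
  to a *t* distribution with the residual degrees of freedom. With a
  plug-in per-gene dispersion the usual normal reference is
  anticonservative at study-sized replication; the *t* reference restores
  the nominal raw-p behaviour, which the test suite verifies against a
  binomial envelope on 2,000 null genes.
* **LRT**: drop the sex column, re-fit at the full model's dispersion,
  chi-square with 1 df.

This is a deliberate trade-off. Per-gene dispersion estimation with a
handful of replicates is noisy, and without borrowing information across
genes (which this package intentionally does not do — no empirical-Bayes
moderation, no fold-change shrinkage, no independent filtering) a
calibrated test necessarily loses sensitivity at very small n relative
to moderation-based tools. The suite quantifies both sides: the null
calibration and false-discovery behaviour pass at the default thresholds,
while sensitivity at n = 4 per sex is substantially below what a
moderated analysis reports. At the design's own replication
(2 populations x 3 replicates per sex) planted 4-fold effects are
recovered reliably.

A gene is sex-biased when BH-adjusted p < 0.05 *and* |log2 FC| >= 1
(2-fold), signed male-over-female. When several sexual populations are
pooled, population enters as an additive covariate.

## Convergent expression shifts

For each expressed single-copy orthologue (SCO), counts of sexual-female
and Amazon gamete samples of both species (males removed) are modelled
with terms `species + mode + species:mode`, with size factors computed
within species. The species factor uses sum-to-zero contrasts, so the
mode term is the Amazon shift averaged over species and the table is
invariant to which species is labelled first; with treatment coding the
drop-one-term tests would depend on the reference level. Each term gets
a 1-df LRT (reduced model re-fitted at the full model's dispersion), and
p-values are BH-adjusted per term across SCOs. A SCO is *convergent*
when the mode term is significant (adjusted p < 0.05) while neither the
species term nor the interaction is (adjusted p >= 0.05; a switch to raw
p is available — the adjusted form was chosen for symmetry with the mode
term). The direction is the sign of the mode coefficient.

The significance of the convergent *count* comes from a block-constrained
permutation: the permutation unit is the (species, population, sex)
block, so replicates of one population always travel together, and
within each species mode labels are shuffled across blocks preserving
the number of sexual and Amazon blocks. Degenerate draws (a species left
with one mode) are redrawn. The empirical p uses the add-one convention
`(1 + #{null >= observed})/(B + 1)`, so it is never zero and never below
`1/(B+1)`. B = 10,000 is the default; the test suite and the
acceptance script use B = 99–199, which is sufficient for calibration
checks at alpha = 0.05.

Overlap between gene sets (e.g. sex-biased genes among convergent SCOs)
is tested exactly: the hypergeometric upper tail for two sets, and for
k > 2 sets the exact distribution of the k-way intersection under
independent uniform draws of fixed-size sets, obtained by convolving the
pairwise kernel.

## Fate of sex-biased genes in Amazons

*Class shifts.* Per bias class, per-gene mean log2(TPM+1) profiles in
sexual females and in Amazons are compared across genes with a two-sided
Mann–Whitney test. Small untied samples use the exact distribution; small
tied samples are enumerated completely (all assignments); otherwise the
tie-corrected normal approximation applies.

*Similarity index.* The reference profile is the per-gene mean of
log2(TPM+1) over all sexual females; each Amazon sample gets one Pearson
r per class. Defeminization appears as a lower r for female-biased genes
than for unbiased genes together with a downward median shift.

*Dependent correlations.* Comparing r(female-biased) with r(unbiased) on
the same samples requires the dependency between the two estimates. The
full Dunn–Clark covariance needs the 4x4 correlation structure of both
profile pairs; this interface deliberately reduces it to a single
exchangeable cross-correlation `r_cross` between the class profiles
(estimated from the sexual-female reference profiles after equalising
class sizes by seeded subsampling and rank-aligning). The covariance term
becomes `2 r_cross^2 / (1 + rbar)^2` with `rbar` the backtransformed
average correlation (Silver–Hittner), and the statistic reduces exactly
to the independent two-sample Fisher-z test at `r_cross = 0`. Zou-style
confidence intervals are reported alongside.

*Regression to the mean.* Genes called male-biased in a male-vs-Amazon
contrast are re-examined between sexual females and Amazons. If the
apparent defeminization were a pure regression-to-the-mean artefact,
this control set would behave like the original male-biased set; the
direction and p of the control shift are reported so the reader can make
that comparison.

## Diversity and selection efficacy

Variants enter as haploid biallelic calls (multi-allelic records are
split on read-in). For diversity estimation a site is kept when at least
2 group samples carry the alternate allele at depth >= 7 and the site
quality is >= 20 (all thresholds inclusive; calls below depth 7 count as
missing). Per site, `pi = n/(n-1) * 2p(1-p)` over the `n` called haploid
samples — exactly the mean pairwise difference, which the tests verify
against an O(n^2) oracle.

Site classification substitutes the alternate base into the reference
codon (reverse-complementing on minus-strand genes; coordinates are
1-based inclusive at the VCF/GFF boundary) and compares translations;
stop gain/loss counts as nonsynonymous. Synonymous and nonsynonymous
*site counts* per gene use NG86 counting: each codon contributes
(synonymous single-base changes)/3 to S and the rest to N, so S + N =
3 x codons; stop-creating changes count as nonsynonymous. A terminal
stop codon and ambiguous codons are skipped. Codons carrying two
variants are classified per variant against the reference codon
(sequential resolution; such codons are rare at study-like diversity).

Per gene and group, `pi_s = sum(site pi over synonymous sites)/S` and
likewise `pi_n`; the ratio is undefined when `pi_s = 0`, and such genes
are excluded from ratio models (a group-level aggregate is also
available in the stage tables).

Group comparisons use the natural model family for this design: Gaussian LMMs (ML)
of pi_s and piN/piS on reproductive mode with log-expression as
covariate and a gene random intercept, tested by 1-df LRTs (singular
fits fall back to ordinary regression, flagged); binomial GLMs for SNP
presence and for variable-site fractions (denominator: CDS length — the
natural choice given variants are classified on CDS), with an optional
gene-random-intercept GLMM fitted by adaptive Gauss–Hermite quadrature.
Model fitting is delegated to `lme4` and `stats::glm`; the test suite
checks the reported likelihoods against direct numeric-integration
oracles.

Haploid-specific (gametophyte-specific) genes are those above 0.4 TPM in
at least `ceiling(4/6 * n)` gametophyte libraries and in no sporophyte
library. Their piN/piS is compared with non-specific genes by
Mann–Whitney — the haploid-purifying-selection readout.

## Amazon-associated variants

The candidate cascade keeps a site when (i) *every* Amazon sample
carries the alternate allele with depth >= 9 and >= 7 alt-supporting
reads, (ii) *every* sexual sample is callable (depth >= 9) and carries
the reference (a missing call rejects the site — the conservative
automation of a manual alignment re-inspection), and (iii) the position
lies on an exon feature. Each stage logs its rejection count and the
audit sums to the input size. The cross-species step intersects
candidate-bearing genes through the orthologue map, by default for
nonsynonymous (missense-focus) candidates only; positions need not be
homologous.

## Divergence rates

Pairwise dN/dS between aligned orthologue CDS uses the NG86 counting
estimator: site counts averaged over the two sequences, observed
differences resolved by averaging over all minimal substitution pathways
per codon (pathways through stop codons excluded; if every pathway hits
a stop, the unrestricted average is used), proportions Jukes–Cantor
corrected (`d = -3/4 log(1 - 4p/3)`, undefined at p >= 3/4). Orthologues
are *valid* for rate comparisons when 0 < dS < 2. The counting estimator
stands in for the usual ML codon models (codeml-style, F3x4
frequencies): it is desk-scale, dependency-free and has an exact
enumeration oracle; systematic offsets against ML estimates are
expected, so ML-derived omega values are qualitative expectations here,
not exact targets. Class-wise comparisons
(bias classes, convergent vs non-convergent) are Mann–Whitney on valid
omegas.

## The synthetic-data generator

The generator emulates the study design rather than any particular
dataset: 2 species; per species 2 sexual populations contributing 3
female and 3 male gamete libraries each and 2 Amazon populations
contributing 3 female libraries each; plus 3 gametophyte libraries per
sex and 3 sporophyte libraries for the generation-specific analysis.
Counts are NB with `Var = mu + 0.2 mu^2`, log-normal baseline abundances
(sdlog 1.5), library sizes log-normal around 5e5. Planted effects:
<1% sex-biased genes (log2 FC 2 in the favoured sex, sexual gametes
only), 6.7% of SCOs with a convergent Amazon shift (log2 FC 2, same sign
in both species), and 10% haploid-specific genes (zero mean in
sporophytes). SCO pairs share their baseline mean across species —
without that conserved-expression assumption the species term of the
convergence model would fire for nearly every SCO and the "unaffected by
species" criterion would be vacuous.

CDS are uniform random sense codons with a terminal stop; ~30% of genes
have two exons and ~20% sit on the minus strand, exercising the
coordinate and strand logic. Orthologue pairs are emitted aligned: the
second species' CDS is evolved from the first at a 0.2 per-site attempt
rate with nonsynonymous attempts accepted at 0.25 (purifying selection),
giving dS around 0.2 and omega around 0.2 — the magnitude regime of the
study system. Variant tables plant a 5:1 sexual:Amazon per-site
diversity contrast (theta 0.01 vs 0.002), purifying selection on
segregating nonsynonymous variation (acceptance 0.3, halved again on
haploid-specific genes, putting piN/piS in the 0.2–0.4 range), and 16
Amazon-fixed missense candidates per species of which exactly one lies
on a shared SCO. Depth is floored at 10 reads and alt reads equal depth
for alt calls, so planted candidates always satisfy the cascade's
callability requirements. All draws derive from a single seed through
fixed substreams, so each generator stage is independently reproducible;
truth labels are written to disk but never read by analysis code.

What the generator does *not* emulate: mapping artefacts, indels,
linked selection, expression-diversity correlations, batch effects, or
any real library-size distribution. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated generative model, not performance on real RNA-seq.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale versions of the
study design: 40–2,000 genes, 15–400 SCOs, B = 99–199 permutations,
20–50 Monte-Carlo replicates — sizes chosen so the full suite completes
in minutes while keeping the calibration checks statistically meaningful
(binomial envelopes at 2,000 genes / 50 datasets). The pipeline defaults
(n_genes = 1200, n_sco = 400, B = 10,000) reflect a realistic scale of
the study system; the acceptance script lowers B to 199.

Other numerical conventions: dispersion floor 1e-8; IRLS capped at 50
iterations at relative tolerance 1e-8 with linear-predictor clamping at
|eta| <= 30; golden-section search for the dispersion on log scale in
[1e-8, 1e3]; LMM singular fits detected at tolerance 1e-5 and flagged;
complete separation in binomial GLMs triggers a +0.5
continuity-corrected refit, flagged; empirical p-values use the add-one
convention throughout.

## Known limitations

* Sensitivity of the sex-bias caller at very small replication is
  bounded by honest per-gene dispersion estimation (see above).
* Codons with co-occurring variants are resolved sequentially rather
  than by pathway averaging within polymorphism data.
* The dependent-correlation comparison compresses the cross-class
  dependency into one exchangeable parameter.
* dN/dS is a counting estimate; no codon frequency model, no branch or
  site models.
* The Gaussian LMM treats piN/piS as unbounded; very sparse groups with
  few defined ratios can make the gene random intercept unidentifiable
  (the fallback path handles this, flagged).
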