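---
title: "Compartment-matched codon-usage analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-matched codon-usage analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What this package computes

`mitocub` quantifies synonymous codon-usage bias (CUB) in paired
mitochondrial and nuclear coding-sequence sets and asks two questions of
the data: how much of the bias is explained by mutation pressure versus
translational selection, and whether the codon preferences of the two
genomic compartments of a species are coupled (coadapted) or independent
(decoupled). The package covers the whole path from GenBank/FASTA input
through QC, per-gene statistics, multivariate structure, and the
per-species coadaptation classification, plus a mutation–selection
simulator that generates cohorts with known ground truth so every stage
can be validated by parameter recovery.

## Estimators

**RSCU.** For codon $j$ of amino acid $i$ with $n_i$ synonyms,
$\mathrm{RSCU}_{ij} = X_{ij}\, n_i / \sum_j X_{ij}$. Values are 1 under
equal use; the conventional strong-preference flag fires at
$\mathrm{RSCU} \ge 1.5$. Codons of families never observed in a unit are
reported as missing, not zero; only when a species-by-codon matrix is
assembled are they imputed as 0 (a species using none of a family's codons
genuinely under-uses them), with the imputation count logged.

**ENC.** Wright's effective number of codons is computed from family
homozygosities $\hat F = (n\sum \hat p^2 - 1)/(n-1)$ averaged within
degeneracy classes, with the class structure derived from the *active*
genetic code rather than hard-coded: under the invertebrate mitochondrial
code (NCBI table 5) serine is 8-fold, tryptophan and methionine become
2-fold, and there are no single-codon families, so the attainable maximum
is 62 rather than 61. Per-class family counts come from the code (9/1/5/3
for the standard code); a class with no usable family is imputed as the
mean of adjacent class averages when both exist, mirroring the classical
treatment of an absent 3-fold class, and flagged low-confidence otherwise.
Family estimates at or below zero are floored at $1/k$. Estimates are
capped at the code's sense-codon count.

**Positional GC.** GC1/GC2/GC3 are raw per-position G+C fractions over
non-ambiguous bases; GC12 is their first/second mean. GC3s restricts the
third position to synonymously variable codons (stops and single-codon
families excluded). Both GC3 and GC3s are always reported: the neutrality
regression uses raw GC3, the ENC diagnostics use GC3s. The two are often
conflated in the CUB literature; keeping both avoids a silent choice.

**Skews.** AT-skew $=(A-T)/(A+T)$ and GC-skew $=(G-C)/(G+C)$ on the coding
strand; a zero denominator yields a missing value with a reason, not a
zero.

**CAI.** Relative adaptiveness weights are per-family count ratios to the
most frequent codon, with zero reference counts replaced by a 0.5
pseudo-count (the classical smoothing convention) so weights stay in
$(0,1]$; CAI is the geometric mean of weights over a gene's codons,
excluding stops and single-codon families. In the default self-referenced
mode the reference set is the pooled counts of the species' own 13
mitochondrial protein-coding genes, so CAI measures within-genome relative
adaptation, not expression-calibrated optimization — genes absent from a
species yield a missing CAI (a `zero_absent_cai` switch writes 0 instead for
table layouts that use zeros).

## Selection-versus-mutation diagnostics

**ENC–GC3 deviation.** $D = \mathrm{ENC}_{exp}(\mathrm{GC3s}) -
\mathrm{ENC}$ with $\mathrm{ENC}_{exp}(x) = 2 + x + 29/(x^2 + (1-x)^2)$;
positive $D$ means bias stronger than composition predicts. Genes shorter
than 100 codons are excluded from these points (QC policy
`min_codons_for_enc`).

**Neutrality regression.** OLS of GC12 on GC3 with a nonparametric
bootstrap that resamples genes with replacement *within* species
(percentile 95% CI; B defaults to 10 000; all seeded, default seed 12345).
Two regression units are provided and the choice matters:

* *gene-level* points carry third-position binomial sampling noise, which
  attenuates the OLS slope by roughly
  $\mathrm{var}(truth)/(\mathrm{var}(truth)+\mathrm{var}(noise))$ — about
  3% at 300-codon genes over a GC3 spread of U(0.2, 0.8). This is an
  errors-in-variables artifact, not biology.
* *species-level* points are codon-weighted means of the species' genes
  (the concatenation summary), which removes nearly all attenuation.

A second, smaller effect is intrinsic to coding sequence: a legitimate CDS
generator draws sense codons only, and excluding the stop triplets from
the 64-codon product distribution makes expected GC12 a slightly sublinear
function of expected GC3. Computed exactly from the model distribution,
the structural slope over GC propensities in (0.2, 0.8) is 0.986 under the
standard code (0.973 under table 5), not 1. Consequently a *pure-mutation*
cohort recovers a slope near but measurably below 1 (about 0.96 at gene
level, 0.98 at species level), and a tight gene-within-species bootstrap
CI around those values does not cover 1.0 exactly. The package reports the
slope and CI as measured; the neutral benchmark should be read with this
known ceiling in mind.

**Group tests.** Order-level differences in gene-wise metrics use
Kruskal–Wallis tests with Benjamini–Hochberg adjustment across the metric
family tested in one invocation; the family size is part of the output so
the adjustment family cannot drift silently.

## Multivariate structure

Species-by-codon RSCU matrices use a fixed amino-acid-grouped column
order. Two codon sets are provided because the "right" set is genuinely
ambiguous: `standard_60` (standard-code sense codons minus ATG, 60
columns, regardless of the data's code) and `code_aware` (the active
code's degenerate sense codons; 62 under table 5, including TGA). Columns
are z-scored (zero-variance columns dropped and listed), PCA is computed
by SVD of the column-centered matrix (correlation-matrix PCA on z-scored
input) with a deterministic sign convention (largest-magnitude loading per
component non-negative) and factor-analysis style diagnostics (percent
contribution and cos²). PERMANOVA on Euclidean distances partitions the
squared-distance matrix; the permutation p-value uses the +1 correction
under free label permutation, or exact enumeration of all distinct label
assignments for small designs. Homogeneity of dispersion is checked with
`vegan::betadisper`/`permutest`. Heat-map row order comes from
complete-linkage hierarchical clustering on Euclidean distances.

## Mitonuclear coadaptation

Per species, the mitochondrial and nuclear RSCU vectors are compared over
the 59 shared degenerate standard-code codons (ATG, TGG and stops
excluded; a code-aware set is available): Pearson $r$, Spearman $\rho$,
and a normalized mutual-information statistic $|M|$. The default rule
classifies *coadapted* at $r \ge 0.7$ and *decoupled* at $r < 0.2$;
0.7 is the conventional benchmark, while 0.2 is this package's
operationalization of "near zero" and is configurable. $|M|$ is computed
by rank-based equal-frequency binning (4 bins; ties broken by codon label
so the statistic is a pure function of its inputs), plug-in MI on the
joint histogram, normalized by the smaller marginal entropy with 0/0
defined as 0. This construction is deterministic, bounded in [0, 1],
attains 1 exactly when one vector is a monotone transform of the other,
and is invariant to monotone transforms — properties chosen because the
underlying dependence statistic for mitonuclear codon landscapes is not
standardized in the literature; $|M|$ here is an interpretation, not a
reproduction of any particular published estimator, and it is always
reported alongside $r$ rather than entering the default classification.

## The simulator and what it does (not) emulate

Codon probabilities follow a mutation–selection balance
$p(c) \propto m(c)\, w(c)^S$: $m(c)$ is the product over the codon's three
positions of nucleotide propensities set by a GC propensity and AT/GC skew
parameters; $w$ are per-codon preference weights (unit mean within each
family); $S \ge 0$ is the selection strength. $S=0$ reduces to the pure
mutational distribution and large $S$ concentrates each family on its
preferred codon.

Two composition modes exist because two different study questions need
them. With *fixed* composition (the default), the amino-acid sequence is
drawn from a fixed, hydrophobic-leaning composition shared across
compartments, so codon-level contrasts are not confounded by protein
composition; positions 1–2 are then pinned and the cohort's GC12~GC3
slope collapses toward 0 by construction. With *free* composition, codons
are drawn from the whole-sense-codon distribution, amino-acid identity is
emergent, all three positions track the mutational process, and a neutral
cohort recovers a slope near 1 (see the structural ceiling above). Neutral
benchmarks use free composition; recovery benchmarks for RSCU structure
and coadaptation use fixed composition.

Cohort defaults are the package's study conditions, chosen once: an
AT-rich mitochondrial preset (GC propensity 0.25, AT-skew −0.40, GC-skew
+0.35, table 5) against a balanced nuclear preset (0.45, +0.05, +0.04,
table 1); per-codon log-preference species effects with SD 1.0 and
order-level effects with SD 0.5 (giving PCA/PERMANOVA recoverable order
structure); 30 species in 3 orders, 13 mitochondrial genes and 30 nuclear
transcripts of 150–520 codons. The default selection strength is 1.5:
the generator's contract is that its defaults support parameter recovery —
shared-preference cohorts classify coadapted in ≥90% of species and
independent-preference cohorts decoupled in ≥80% — and 1.5 is the
moderate value satisfying those margins across seeds, given that the two
compartments' different mutational regimes decorrelate RSCU vectors when
selection is much weaker.

The simulator emulates compositional regimes, strand skews,
order-structured preferences and compartment coupling. It does *not*
emulate phylogenetic autocorrelation (species are exchangeable within
orders), real mitochondrial gene-length distributions or gene order,
tRNA/rRNA genes, within-genome expression-linked heterogeneity, or
sequencing error beyond uniform ambiguity. Tests passing on these cohorts
therefore validate the estimators and the recovery logic, not claims about
any particular real lineage.

## Numerical and procedural choices

* GenBank 1-based inclusive coordinates convert to 0-based half-open at
  the parser boundary, once. Minus-strand features are
  reverse-complemented into coding orientation on read.
* "Frameshift" is operationalized as length not divisible by 3 after
  trimming a trailing incomplete stop codon (1–2 nt overhang matching a
  stop prefix, mitochondrial genes only) — the only sequence-intrinsic
  test available; trims are logged, not rejected.
* QC order: ambiguity (> 1% N), nuclear minimum length (150 nt), overhang
  trim, frameshift, internal stops under the record's own code. Filtering
  is total and idempotent.
* Concatenation preserves the exact in-order codon sequence so codon
  counts of the whole equal the sum of the parts; stop codons stay in
  place and are excluded from metrics at the counting stage.
* Gene-name normalization uses an explicit synonym table onto the 13
  canonical labels; unmatched CDSs keep their raw name and simply fall
  outside canonical-gene summaries.
* All permutation and bootstrap procedures take explicit seeds (default
  12345) and restore the caller's RNG state; pipeline reruns with the same
  config and inputs are byte-identical.
* PERMANOVA p-values use the +1 correction for random permutations and
  plain enumeration fractions in exhaustive mode; tied F values are
  counted as exceedances (within 1e−12).

## Problem sizes used in validation

The shipped test-suite and benchmark runs are sized for a desk-scale
machine and chosen as the package's own validation design: neutral-slope
recovery uses 30 species × 50 genes × 300 codons with B = 2000 bootstrap
replicates; coadaptation recovery uses 10–20 species with ≥ 3500–5000
codons per compartment; the PERMANOVA/Kruskal–Wallis type-I-error check
uses 500 null simulations at 199 permutations each (p-value resolution
0.005, ample for a rejection-rate check at α = 0.05); bootstrap-coverage
spot checks use reduced cohort counts. Scaling any of these up changes
precision, not conclusions, with the one documented exception of the
neutral-slope structural ceiling discussed above.

## Known limitations

* The GenBank parser covers the feature subset this analysis needs (CDS
  features, complement/join locations, gene/product/transl_table
  qualifiers); it is not a general GenBank reader.
* CAI without an expression-calibrated reference measures within-genome
  relative adaptation only.
* $|M|$ with 4 equal-frequency bins over 59 codons has a positive plug-in
  bias under independence (small-sample MI bias); it is reported for
  ranking and regime contrasts, and the classification deliberately rests
  on $r$.
* ENC for very short or family-sparse genes relies on class imputation
  and is flagged low-confidence rather than suppressed.
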