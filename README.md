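# mitocub

Compartment-matched codon-usage bias analysis for mitochondrial genomes
and nuclear transcriptomes.

Synonymous codons are used non-randomly, and the bias is informative: in
animal mitochondria it is dominated by strand-asymmetric, AT-rich mutation
pressure, while nuclear coding sequence often carries the signature of
translational selection. For organisms whose respiratory chain is
assembled from both genomes — parasitic helminths being a prime example —
the interesting questions are *how much* of the bias each force explains
in each compartment, and whether the two compartments' codon preferences
are coupled (coadapted) or independent (decoupled). `mitocub` is an R
package plus a set of analysis drivers that answers these questions for
any collection of species with a mitochondrial CDS set (GenBank flat
files) and a nuclear CDS set (FASTA), and ships a mutation–selection
simulator that generates ground-truth cohorts so every stage is testable
by parameter recovery.

## What it computes

* **Codon-usage metrics** per gene or concatenated species/compartment
  unit: codon counts; RSCU (`RSCU_ij = X_ij · n_i / Σ_j X_ij`, 1 = no
  bias, ≥ 1.5 flagged as strong preference); Wright's effective number of
  codons with degeneracy classes derived from the active genetic code
  (ENC ∈ (20, 61] for the standard code, up to 62 under the invertebrate
  mitochondrial code); positional GC (GC1/GC2/GC3, GC12, GC3s);
  AT/GC strand skews; CAI as the geometric mean of relative adaptiveness
  weights, self-referenced against the species' own pooled mitochondrial
  genes by default.
* **Selection vs mutation**: deviation from Wright's neutral expectation
  `ENC_exp = 2 + GC3s + 29/(GC3s² + (1−GC3s)²)`; the GC12~GC3 neutrality
  regression (slope ≈ 1 ⇒ mutation-driven, ≪ 1 ⇒ selective constraint at
  positions 1–2) with a gene-within-species bootstrap CI; Kruskal–Wallis
  order-level tests with Benjamini–Hochberg correction.
* **Multivariate structure**: species-by-codon RSCU matrices (60-codon
  standard set or code-aware), column z-scoring, correlation-matrix PCA
  with contribution/cos² diagnostics, PERMANOVA on Euclidean distances
  (seeded random or exhaustive permutations) with a dispersion-homogeneity
  check, complete-linkage clustering for heat-map ordering.
* **Mitonuclear coadaptation**: per-species Pearson/Spearman correlation
  of the two compartments' RSCU vectors over the 59 shared degenerate
  codons, a normalized mutual-information statistic |M| ∈ [0, 1], and the
  coadapted (r ≥ 0.7) / intermediate / decoupled (r < 0.2) classification.
* **Synthetic cohorts**: `p(codon) ∝ m(codon) · w(codon)^S` per family,
  where `m` is a positionwise mutational propensity (GC bias + AT/GC
  skews) and `w` are preference weights; presets emulate the AT-rich,
  skewed mitochondrial regime (translation table 5) against a balanced
  nuclear regime (table 1), with order-structured preferences and
  shared-vs-independent compartment coupling, written out as GenBank +
  FASTA + a ground-truth manifest.

## Worked example

```r
library(mitocub)

cohort <- generate_cohort(cohort_spec(n_species = 4, seed = 12345))
sp <- cohort$species[[1]]

mito <- concatenate_cds(sp$mito_genes)
counts <- count_codons(mito)
gc <- positional_gc(mito)
cat(sprintf("%s mito: %d codons | ENC %.2f | GC3s %.3f\n",
            sp$species_id, counts$total_codons,
            as.numeric(compute_enc(counts)), gc[["gc3s"]]))
cat(sprintf("  expected ENC at this GC3s: %.2f -> deviation D = %.2f\n",
            enc_expected(gc[["gc3s"]]),
            enc_expected(gc[["gc3s"]]) - as.numeric(compute_enc(counts))))

w <- reference_weights(sum_codon_counts(lapply(sp$mito_genes, count_codons)))
cai <- vapply(sp$mito_genes, function(g) compute_cai(count_codons(g), w),
              numeric(1))
cat(sprintf("  self-referenced CAI, COX1: %.3f | ATP8: %.3f\n",
            cai[[3]], cai[[2]]))

profs <- function(field) {
  out <- lapply(cohort$species, function(s) {
    p <- compute_rscu(count_codons(concatenate_cds(s[[field]])))
    p$unit_id <- s$species_id; p })
  setNames(out, vapply(cohort$species, `[[`, character(1), "species_id"))
}
coad <- coadaptation_table(profs("mito_genes"), profs("nuclear_genes"))
print(coad[, c("species_id", "r_pearson", "m_norm", "class_label")],
      digits = 3)
```

prints

```
sp001 mito: 4441 codons | ENC 33.88 | GC3s 0.330
  expected ENC at this GC3s: 54.34 -> deviation D = 20.46
  self-referenced CAI, COX1: 0.767 | ATP8: 0.736
  species_id r_pearson m_norm class_label
1      sp001     0.724  0.325   coadapted
2      sp002     0.877  0.507   coadapted
3      sp003     0.871  0.351   coadapted
4      sp004     0.900  0.469   coadapted
```

Reading it: the species' concatenated mitochondrial genes use far fewer
effective codons (ENC 33.9) than composition alone predicts at GC3s 0.33
(expected 54.3), i.e. the simulated translational selection pushed the
genes well below Wright's curve (D ≈ +20). CAI is relative to the
species' own pooled mitochondrial reference, so values near the top of
the cohort's range (COX1 0.77) mark genes whose codon usage sits closest
to the genome's preferred set. This cohort was generated with shared
preference vectors, and all four species are correctly recovered as
coadapted (r > 0.7), with the dependence statistic |M| reported alongside.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
cohort and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort -> results/cohort/ (GenBank, FASTA, manifest)
Rscript analysis/02_codon_usage.R   # QC, metrics, RSCU, PCA, PERMANOVA -> results/analysis/
Rscript analysis/03_selection.R     # ENC-GC3, neutrality slopes, order tests -> results/selection/
Rscript analysis/04_coadaptation.R  # coadaptation vs a decoupled contrast cohort, report
```

Every stage is a thin wrapper over exported package functions
(`run_pipeline()` orchestrates the whole sequence from a
`pipeline_config()`, optionally read from YAML), so the same computations
are available programmatically on real data: point `pipeline_config()`'s
`input_dir` at a directory with a `metadata.tsv` (species_id, order_label,
mito_path, nuclear_path) referencing your GenBank/FASTA files.

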