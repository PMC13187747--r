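Package: mitocub
Title: Compartment-Matched Codon Usage Bias Analysis for Mitochondrial
    and Nuclear Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying synonymous codon usage bias in
    mitochondrial genomes and matched nuclear transcriptomes: relative
    synonymous codon usage (RSCU), Wright's effective number of codons
    (ENC) with code-aware degeneracy classes, codon adaptation index
    (CAI) with self-referenced adaptiveness weights, positional GC
    content, and AT/GC strand skews. Includes selection-versus-mutation
    diagnostics (ENC-GC3 deviation from Wright's neutral expectation,
    GC12-on-GC3 neutrality regression with gene-within-species
    bootstrap), multivariate structure analysis (correlation-matrix PCA,
    PERMANOVA with exhaustive or seeded permutations, dispersion
    homogeneity, hierarchical clustering), per-species mitonuclear
    coadaptation statistics (RSCU correlation and normalized mutual
    information), and a seeded mutation-selection cohort simulator with
    a ground-truth manifest for parameter-recovery testing. Reads CDS
    sets from GenBank flat files and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
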