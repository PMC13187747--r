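test_that("codon distributions obey the mutation-selection limits", {
  # S = 0, balanced composition, zero skews: 2-fold family is uniform
  m0 <- compartment_model(gc_bias = 0.5)
  expect_equal(unname(codon_distribution(m0, "E")), c(0.5, 0.5))
  expect_equal(sum(codon_distribution(m0, "L")), 1)

  # gc_bias -> 1 pushes mass onto the G/C-ending codon of an A/G pair
  m1 <- compartment_model(gc_bias = 0.99)
  p <- codon_distribution(m1, "E")  # GAA vs GAG
  expect_gt(p[["GAG"]], 0.97)

  # large S with preference on GAA concentrates there
  code <- load_genetic_code(1)
  w <- stats::setNames(rep(1, 61), code$sense_codons)
  w[c("GAA", "GAG")] <- c(1.8, 0.2) / 1  # unit mean in family
  ms <- compartment_model(gc_bias = 0.5, selection_strength = 25,
                          preference_weights = w)
  expect_gt(codon_distribution(ms, "E")[["GAA"]], 0.99)

  expect_error(codon_distribution(m0, "B"), "not in code")
})

test_that("gene generation is seeded, stop-free and QC-clean by construction", {
  m <- preset_model("mito")
  g1 <- generate_gene(m, 200, seed = 5)
  g2 <- generate_gene(m, 200, seed = 5)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence) %% 3, 0)
  code <- load_genetic_code(5)
  codons <- split_codons(g1$sequence)
  expect_false(any(codons[-length(codons)] %in% code$stop_codons))
  expect_true(codons[length(codons)] %in% code$stop_codons)
  # all 20 amino acids present for length >= 100 (fixed mode)
  aas <- unique(code$codon_to_aa[codons[-length(codons)]])
  expect_length(setdiff(names(code$families), aas), 0)
  # passes default QC
  expect_length(qc_filter(list(g1))$retained, 1)
})

test_that("neutral GC3 matches the analytic expectation of the model", {
  m <- compartment_model(gc_bias = 0.2)
  p <- mitocub:::sense_codon_distribution(m)
  third <- substring(names(p), 3, 3)
  expected_gc3 <- sum(p[third %in% c("G", "C")])
  set.seed(6)
  gc3s <- replicate(30, {
    positional_gc(generate_gene(m, 400, composition = "free"))[["gc3"]]
  })
  # binomial tolerance: se of the mean ~ sqrt(p(1-p)/(400*30))
  expect_equal(mean(gc3s), expected_gc3, tolerance = 0.02)
})

test_that("neutral genes track Wright's curve; selection pulls ENC below it", {
  set.seed(61)
  ds <- replicate(20, {
    g <- generate_gene(compartment_model(gc_bias = runif(1, 0.2, 0.8)),
                       350, composition = "free")
    gc <- positional_gc(g)
    enc_expected(gc[["gc3s"]]) - as.numeric(compute_enc(count_codons(g)))
  })
  expect_lte(mean(abs(ds)), 3)

  # sparse preference vector under selection: ENC falls below the curve
  code <- load_genetic_code(1)
  w <- stats::setNames(rep(1, 61), code$sense_codons)
  for (fam in code$families) {
    v <- rep(0.1, length(fam))
    v[1] <- 1
    w[fam] <- v / mean(v)
  }
  set.seed(62)
  ds_sel <- replicate(10, {
    m <- compartment_model(gc_bias = 0.5, selection_strength = 2,
                           preference_weights = w)
    g <- generate_gene(m, 350, composition = "free")
    gc <- positional_gc(g)
    enc_expected(gc[["gc3s"]]) - as.numeric(compute_enc(count_codons(g)))
  })
  expect_gt(mean(ds_sel), 3)
})

test_that("cohorts are deterministic under a fixed spec seed", {
  spec <- cohort_spec(n_species = 4, nuclear_genes_per_species = 5,
                      gene_length_codons = c(120L, 200L), seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  s1 <- vapply(c1$species, function(s) s$mito_genes[[1]]$sequence,
               character(1))
  s2 <- vapply(c2$species, function(s) s$mito_genes[[1]]$sequence,
               character(1))
  expect_identical(s1, s2)
  expect_identical(c1$truth$per_species[[2]]$pref_mito,
                   c2$truth$per_species[[2]]$pref_mito)
})

test_that("default cohort presets land in the mito/nuclear compositional regimes", {
  coh <- generate_cohort(cohort_spec(n_species = 6,
                                     nuclear_genes_per_species = 10,
                                     seed = 7))
  at_of <- function(genes) {
    s <- concatenate_cds(genes)$sequence
    mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  }
  at_m <- vapply(coh$species, function(s) at_of(s$mito_genes), numeric(1))
  at_n <- vapply(coh$species, function(s) at_of(s$nuclear_genes), numeric(1))
  # mito clearly AT-richer than nuclear, both AT-biased
  expect_true(all(at_m > at_n))
  expect_gt(mean(at_m), 0.62)
  sk <- vapply(coh$species, function(s) {
    compute_skews(concatenate_cds(s$mito_genes))
  }, numeric(2))
  # mito preset: negative AT skew (T > A), positive GC skew (G > C)
  expect_true(all(sk["at_skew", ] < 0))
  expect_true(all(sk["gc_skew", ] > 0))
  # genetic codes per compartment
  expect_equal(coh$species[[1]]$mito_genes[[1]]$table_id, 5L)
  expect_equal(coh$species[[1]]$nuclear_genes[[1]]$table_id, 1L)
})

test_that("order-structured preferences give PERMANOVA-recoverable clusters", {
  coh <- generate_cohort(cohort_spec(n_species = 30,
                                     orders = c("O1", "O2", "O3"),
                                     nuclear_genes_per_species = 2,
                                     gene_length_codons = c(200L, 300L),
                                     seed = 31))
  profs <- lapply(coh$species, function(sp) {
    p <- compute_rscu(count_codons(concatenate_cds(sp$mito_genes)))
    p$unit_id <- sp$species_id
    p
  })
  z <- zscore_columns(assemble_matrix(profs, "standard_60"))
  labs <- vapply(coh$species, `[[`, character(1), "order_label")
  res <- permanova(z, labs, permutations = 999, seed = 1)
  expect_lt(res$p_value, 0.01)
})

test_that("cohorts round-trip through the GenBank/FASTA writers and readers", {
  dir <- tempfile("cohort")
  coh <- generate_cohort(cohort_spec(n_species = 3,
                                     nuclear_genes_per_species = 4,
                                     gene_length_codons = c(100L, 150L),
                                     seed = 13))
  meta <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  sp1 <- coh$species[[1]]
  back <- read_genbank_cds(meta$mito_path[1])
  expect_length(back, length(sp1$mito_genes))
  expect_identical(vapply(back, `[[`, character(1), "sequence"),
                   vapply(sp1$mito_genes, `[[`, character(1), "sequence"))
  expect_identical(vapply(back, `[[`, character(1), "gene"),
                   vapply(sp1$mito_genes, `[[`, character(1), "gene"))
  nuc <- read_fasta_cds(meta$nuclear_path[1])
  expect_identical(vapply(nuc, `[[`, character(1), "sequence"),
                   vapply(sp1$nuclear_genes, `[[`, character(1), "sequence"))
  expect_equal(nuc[[1]]$species_id, sp1$species_id)
})
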