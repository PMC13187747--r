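test_that("codon counting is frame-0, excludes N codons and tracks stops", {
  cc <- count_codons("ATGAAATTT")
  expect_equal(unname(cc$counts[c("ATG", "AAA", "TTT")]), c(1L, 1L, 1L))
  expect_equal(cc$total_codons, 3L)

  cc2 <- count_codons("AANAAA")
  expect_equal(unname(cc2$counts[["AAA"]]), 1L)
  expect_equal(cc2$ambiguous, 1L)
  expect_equal(cc2$total_codons, 1L)

  cc3 <- count_codons("ATGTAA")  # stop excluded from sense totals
  expect_equal(cc3$total_codons, 1L)
  expect_equal(unname(cc3$stop_counts[["TAA"]]), 1L)

  expect_error(count_codons("ATGA"), "multiple of 3")
})

test_that("RSCU matches its definition on hand-checkable families", {
  r <- compute_rscu(codon_counts_from_vector(c(GAA = 2, GAG = 2)))
  expect_equal(unname(r$rscu[c("GAA", "GAG")]), c(1, 1))

  r2 <- compute_rscu(codon_counts_from_vector(c(GAA = 3, GAG = 1)))
  expect_equal(unname(r2$rscu[c("GAA", "GAG")]), c(1.5, 0.5))

  # 4-fold family used through a single codon: max equals family size
  r3 <- compute_rscu(codon_counts_from_vector(c(GCT = 4)))
  expect_equal(unname(r3$rscu[c("GCT", "GCC", "GCA", "GCG")]), c(4, 0, 0, 0))

  # unobserved families are NA, not 0
  expect_true(is.na(r3$rscu[["GAA"]]))
})

test_that("RSCU family sums equal family sizes on random fixtures", {
  set.seed(101)
  for (i in 1:20) {
    tid <- sample(c(1L, 5L), 1)
    code <- load_genetic_code(tid)
    cc <- count_codons(random_gene_seq(sample(20:200, 1), tid), tid)
    r <- compute_rscu(cc)
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      if (sum(cc$counts[fam]) > 0) {
        expect_equal(sum(r$rscu[fam]), length(fam))
        expect_true(all(r$rscu[fam] >= 0 & r$rscu[fam] <= length(fam)))
      } else {
        expect_true(all(is.na(r$rscu[fam])))
      }
    }
  }
})

test_that("strong-preference flag fires at the 1.5 boundary", {
  expect_true(rscu_strong_preference(1.5))
  expect_false(rscu_strong_preference(1.499))
  expect_equal(rscu_strong_preference(c(0.5, 1.5, NA, 2)),
               c(FALSE, TRUE, FALSE, TRUE))
})

test_that("ENC attains Wright's bounds on the canonical constructions", {
  std <- load_genetic_code(1)
  # one codon per family, all 20 amino acids, n >= 2 each -> ENC = 20
  one <- vapply(std$families, `[`, character(1), 1)
  enc_min <- compute_enc(codon_counts_from_vector(
    stats::setNames(rep(10L, 20), unname(one))))
  expect_equal(as.numeric(enc_min), 20)
  # equal usage of every sense codon -> raw estimator exceeds 61, capped
  enc_max <- compute_enc(codon_counts_from_vector(
    stats::setNames(rep(12L, 61), std$sense_codons)))
  expect_equal(as.numeric(enc_max), 61)
})

test_that("ENC homozygosity follows Wright's formula on a hand case", {
  # single 2-fold family with counts (3,1): F = (4*0.625 - 1)/3 = 0.5;
  # with only the 2-fold class observed (9 such families in the standard
  # code) and no adjacent classes to impute from, ENC = 2 + 9/0.5 = 20,
  # flagged low-confidence
  enc <- compute_enc(codon_counts_from_vector(c(GAA = 3, GAG = 1)))
  expect_equal(as.numeric(enc), 20)
  expect_true(attr(enc, "low_confidence"))
  expect_error(compute_enc(codon_counts_from_vector(c(ATG = 5))),
               "undefined")
})

test_that("ENC and RSCU agree with brute-force recomputation on 100 random genes", {
  set.seed(2024)
  for (i in 1:100) {
    tid <- sample(c(1L, 5L), 1)
    n <- sample(30:120, 1)
    seq <- random_gene_seq(n, tid)
    codons <- split_codons(seq)
    cc <- count_codons(seq, tid)
    r <- compute_rscu(cc)$rscu
    o <- oracle_rscu(codons, tid)
    expect_equal(r, o[names(r)])
    enc_pkg <- tryCatch(as.numeric(compute_enc(cc)), error = function(e) NA)
    if (!is.na(enc_pkg)) {
      expect_equal(enc_pkg, oracle_enc(codons, tid), tolerance = 1e-12)
    }
  }
})

test_that("positional GC and GC3s follow the degenerate-only rule", {
  gc <- positional_gc("GGGCCC")
  expect_equal(unname(gc[c("gc1", "gc2", "gc3", "gc12")]), c(1, 1, 1, 1))
  expect_equal(unname(positional_gc("AAATTT")[c("gc1", "gc2", "gc3")]),
               c(0, 0, 0))
  # only Met and Trp codons under the standard code: no degenerate codons,
  # so GC3s undefined while raw GC3 is defined
  gc2 <- positional_gc("ATGTGGATG", table_id = 1L)
  expect_true(is.na(gc2[["gc3s"]]))
  expect_equal(gc2[["gc3"]], 1)
  # under table 5 the same codons are degenerate (Met: ATA/ATG; Trp:
  # TGA/TGG), so GC3s is defined
  expect_equal(positional_gc("ATGTGGATG", table_id = 5L)[["gc3s"]], 1)
  expect_equal(unname(positional_gc("GCTGCG")[c("gc12", "gc3s")]), c(1, 0.5))
  expect_equal(positional_gc("GAAAAATTC")[["gc12"]], (1 / 3 + 0) / 2)
})

test_that("skews match their definition and negate under reverse complement", {
  sk <- compute_skews(c(A = 30, T = 10, G = 5, C = 5))
  expect_equal(unname(sk), c(0.5, 0))
  set.seed(5)
  for (i in 1:10) {
    s <- random_gene_seq(50, 1)
    a <- compute_skews(s)
    b <- compute_skews(reverse_complement(s))
    expect_equal(unname(a), -unname(b))
  }
  expect_true(is.na(compute_skews(c(A = 0, T = 0, G = 3, C = 1))[["at_skew"]]))
})

test_that("adaptiveness weights use max-ratio with 0.5 pseudo-count", {
  w <- reference_weights(codon_counts_from_vector(c(GAA = 30, GAG = 10)))
  expect_equal(unname(w$weights[c("GAA", "GAG")]), c(1, 1 / 3))
  w2 <- reference_weights(codon_counts_from_vector(c(GCT = 8)))
  expect_equal(unname(w2$weights[["GCC"]]), 0.5 / 8)
  w3 <- reference_weights(codon_counts_from_vector(
    c(GAA = 5, GAG = 5, AAA = 7, AAG = 7)))
  expect_equal(unname(w3$weights[c("GAA", "GAG", "AAA", "AAG")]), rep(1, 4))
  expect_error(reference_weights(codon_counts_from_vector(c(GAA = 0))),
               "empty reference")
})

test_that("CAI is the geometric mean of weights with the stated exclusions", {
  # reference with a strict most-frequent codon per family
  std <- load_genetic_code(1)
  ref <- integer(0)
  for (fam in std$families) {
    ref[fam] <- c(50L, seq_len(length(fam) - 1L))[seq_along(fam)]
  }
  w <- reference_weights(codon_counts_from_vector(ref))
  best <- vapply(std$families, function(fam) fam[which.max(ref[fam])],
                 character(1))
  gene_best <- codon_counts_from_vector(
    stats::setNames(rep(3L, length(best)), unname(best)))
  expect_equal(compute_cai(gene_best, w), 1)

  # two-codon gene with w = 1 and 0.25 -> sqrt(0.25)
  w2 <- reference_weights(codon_counts_from_vector(c(GAA = 4, GAG = 1)))
  gene2 <- codon_counts_from_vector(c(GAA = 1, GAG = 1))
  expect_equal(compute_cai(gene2, w2), 0.5)

  # geometric-mean scale invariance: doubling counts leaves CAI unchanged
  gene3 <- codon_counts_from_vector(c(GAA = 2, GAG = 2))
  expect_equal(compute_cai(gene3, w2), compute_cai(gene2, w2))

  # gene with no degenerate-family codon -> NA
  geneM <- codon_counts_from_vector(c(ATG = 10))
  expect_true(is.na(compute_cai(geneM, w2)))
})

test_that("CAI is monotone under replacement by a higher-weight synonym", {
  set.seed(9)
  w <- reference_weights(count_codons(random_gene_seq(500, 1), 1L))
  base <- c(GAA = 5L, GAG = 5L, GCT = 4L, GCC = 2L)
  cai0 <- compute_cai(codon_counts_from_vector(base), w)
  # move one count to the higher-w codon of the Glu family
  hi <- if (w$weights[["GAA"]] >= w$weights[["GAG"]]) "GAA" else "GAG"
  lo <- setdiff(c("GAA", "GAG"), hi)
  shifted <- base
  shifted[lo] <- shifted[lo] - 1L
  shifted[hi] <- shifted[hi] + 1L
  expect_gte(compute_cai(codon_counts_from_vector(shifted), w), cai0)
})
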