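# Fixtures built in code and independent brute-force oracles. The oracles
# recompute statistics from raw triplet lists by direct enumeration and are
# deliberately implemented with different code paths from the package.

# random in-frame coding sequence (sense codons only) under a code
random_gene_seq <- function(n_codons, table_id = 1L) {
  code <- load_genetic_code(table_id)
  paste(sample(code$sense_codons, n_codons, replace = TRUE), collapse = "")
}

# brute-force RSCU from a triplet list: for each codon, count / mean count
# of its synonymous family
oracle_rscu <- function(codons, table_id = 1L) {
  code <- load_genetic_code(table_id)
  codons <- codons[codons %in% code$sense_codons]
  out <- numeric(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    cnts <- vapply(fam, function(cd) sum(codons == cd), numeric(1))
    if (sum(cnts) == 0) {
      out[fam] <- NA_real_
    } else {
      out[fam] <- cnts / mean(cnts)
    }
  }
  out
}

# brute-force Wright ENC: homozygosity per family by direct p^2 enumeration,
# class means over code-defined degeneracy classes, adjacent-class
# imputation, cap at the sense-codon count
oracle_enc <- function(codons, table_id = 1L) {
  code <- load_genetic_code(table_id)
  codons <- codons[codons %in% code$sense_codons]
  sizes <- lengths(code$families)
  classes <- sort(unique(sizes[sizes >= 2]))
  fbar <- nfam <- setNames(rep(NA_real_, length(classes)),
                           as.character(classes))
  for (k in classes) {
    fams <- code$families[sizes == k]
    nfam[as.character(k)] <- length(fams)
    fs <- c()
    for (fam in fams) {
      n <- sum(codons %in% fam)
      if (n < 2) next
      f <- 0
      for (cd in fam) f <- f + (sum(codons == cd) / n)^2
      f <- (n * f - 1) / (n - 1)
      if (f <= 0) f <- 1 / k
      fs <- c(fs, f)
    }
    if (length(fs)) fbar[as.character(k)] <- mean(fs)
  }
  for (i in seq_along(classes)) {
    if (is.na(fbar[i]) && i > 1 && i < length(classes) &&
        !is.na(fbar[i - 1]) && !is.na(fbar[i + 1])) {
      fbar[i] <- (fbar[i - 1] + fbar[i + 1]) / 2
    }
  }
  ok <- !is.na(fbar)
  min(sum(sizes == 1) + sum(nfam[ok] / fbar[ok]), code$enc_max)
}

# exhaustive PERMANOVA p by direct enumeration of group assignments
oracle_permanova_exhaustive <- function(x, labels) {
  d2 <- as.matrix(dist(x))^2
  f_stat <- function(lab) {
    n <- nrow(d2)
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in unique(lab)) {
      ix <- which(lab == g)
      sub <- d2[ix, ix, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(ix)
    }
    ssb <- sst - ssw
    g <- length(unique(lab))
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  obs <- f_stat(labels)
  # enumerate index subsets for the first group (two-group case)
  stopifnot(length(unique(labels)) == 2)
  g1 <- sort(unique(labels))[1]
  k <- sum(labels == g1)
  n <- length(labels)
  combs <- utils::combn(n, k)
  fs <- apply(combs, 2, function(ix) {
    lab <- rep(sort(unique(labels))[2], n)
    lab[ix] <- g1
    f_stat(lab)
  })
  # weight: each subset corresponds to one distinct assignment
  mean(fs >= obs - 1e-12)
}

# a tiny GenBank flat-file record built in code
toy_genbank <- function(cds_seqs, strands = rep("+", length(cds_seqs)),
                        genes = paste0("GENE", seq_along(cds_seqs)),
                        transl_table = 5L, organism = "Testus exemplaris") {
  genome <- ""
  feats <- character(0)
  for (i in seq_along(cds_seqs)) {
    s <- cds_seqs[i]
    start1 <- nchar(genome) + 1L
    end1 <- nchar(genome) + nchar(s)
    genome <- paste0(genome,
                     if (strands[i] == "-") {
                       mitocub::reverse_complement(s)
                     } else s)
    loc <- if (strands[i] == "-") {
      sprintf("complement(%d..%d)", start1, end1)
    } else sprintf("%d..%d", start1, end1)
    feats <- c(feats,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", genes[i]),
               sprintf("                     /transl_table=%d", transl_table))
  }
  seq_lines <- character(0)
  for (s in seq(1, nchar(genome), 60)) {
    chunk <- substr(genome, s, min(s + 59, nchar(genome)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    seq_lines <- c(seq_lines,
                   sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))))
  }
  c(sprintf("LOCUS       TEST01 %d bp    DNA     circular     01-JAN-2026",
            nchar(genome)),
    "DEFINITION  synthetic test record.",
    "SOURCE      synthetic",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    feats,
    "ORIGIN",
    seq_lines,
    "//")
}
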