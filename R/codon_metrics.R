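# Per-unit codon-usage statistics: codon counts, RSCU, Wright's ENC,
# positional GC content, AT/GC strand skews, relative adaptiveness weights,
# and the codon adaptation index.

#' Count frame-0 codons of a coding sequence
#'
#' Codons containing `N` are excluded from the counts and tallied as
#' ambiguous; stop codons of the active code are tallied separately and
#' excluded from every downstream metric.
#'
#' @param cds A `cds` object (length a multiple of 3), or a plain sequence
#'   string together with `table_id`.
#' @param table_id Translation table when `cds` is a bare string.
#' @return A `codon_counts` object: list with `unit_id`, `counts` (named
#'   integer over the code's sense codons), `stop_counts`, `ambiguous`,
#'   `total_codons` (sense total) and `code`.
#' @export
count_codons <- function(cds, table_id = NULL) {
  if (inherits(cds, "cds")) {
    seq <- cds$sequence
    table_id <- cds$table_id
    unit_id <- paste(cds$species_id, cds$compartment, cds$gene, sep = "|")
  } else {
    seq <- as.character(cds)
    if (is.null(table_id)) table_id <- 1L
    unit_id <- "unit"
  }
  code <- load_genetic_code(table_id)
  codons <- split_codons(seq)
  ambiguous <- sum(grepl("N", codons))
  clean <- codons[!grepl("N", codons)]
  tab <- table(factor(clean, levels = ALL_CODONS))
  counts <- stats::setNames(as.integer(tab[code$sense_codons]),
                            code$sense_codons)
  stop_counts <- stats::setNames(as.integer(tab[code$stop_codons]),
                                 code$stop_codons)
  structure(
    list(unit_id = unit_id, counts = counts, stop_counts = stop_counts,
         ambiguous = as.integer(ambiguous),
         total_codons = sum(counts), code = code),
    class = "codon_counts"
  )
}

#' Build a codon-count object from a named count vector
#'
#' Convenience constructor for analyses that start from tabulated counts
#' (e.g. pooled reference sets) rather than sequences.
#'
#' @param counts Named non-negative integer vector; names are codons.
#' @param table_id NCBI translation table.
#' @param unit_id Unit label.
#' @return A `codon_counts` object.
#' @export
codon_counts_from_vector <- function(counts, table_id = 1L, unit_id = "unit") {
  code <- load_genetic_code(table_id)
  stopifnot(all(names(counts) %in% ALL_CODONS), all(counts >= 0))
  full <- stats::setNames(integer(length(code$sense_codons)),
                          code$sense_codons)
  keep <- intersect(names(counts), code$sense_codons)
  full[keep] <- as.integer(counts[keep])
  stops <- stats::setNames(integer(length(code$stop_codons)),
                           code$stop_codons)
  keep_s <- intersect(names(counts), code$stop_codons)
  stops[keep_s] <- as.integer(counts[keep_s])
  structure(
    list(unit_id = unit_id, counts = full, stop_counts = stops,
         ambiguous = 0L, total_codons = sum(full), code = code),
    class = "codon_counts"
  )
}

#' Sum codon-count tables
#'
#' @param ... `codon_counts` objects sharing a genetic code.
#' @return Pooled `codon_counts`.
#' @export
sum_codon_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "codon_counts")) {
    xs <- xs[[1]]
  }
  tids <- vapply(xs, function(x) x$code$table_id, integer(1))
  if (length(unique(tids)) != 1L) stop("mixed genetic codes", call. = FALSE)
  out <- xs[[1]]
  if (length(xs) > 1L) {
    for (x in xs[-1]) {
      out$counts <- out$counts + x$counts
      out$stop_counts <- out$stop_counts + x$stop_counts
      out$ambiguous <- out$ambiguous + x$ambiguous
    }
  }
  out$total_codons <- sum(out$counts)
  out$unit_id <- "pooled"
  out
}

#' Relative synonymous codon usage
#'
#' For codon j of amino acid i with n_i synonymous codons,
#' `RSCU_ij = X_ij * n_i / sum_j X_ij`: the observed count relative to the
#' expectation under equal use within the family. RSCU 1 means no bias;
#' values above 1 mark preferred codons (values at or above 1.5 are
#' conventionally flagged as strong preference). Codons of families with
#' zero observations are reported as `NA`, not 0.
#'
#' @param counts A `codon_counts` object.
#' @return An `rscu_profile`: list with `unit_id`, `rscu` (named numeric
#'   over sense codons, `NA` for unobserved families), `family_sizes`
#'   (named integer per amino acid) and `code`.
#' @export
compute_rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- counts$code
  rscu <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                          code$sense_codons)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(counts$counts[fam])
    if (tot > 0) {
      rscu[fam] <- counts$counts[fam] * length(fam) / tot
    }
  }
  structure(
    list(unit_id = counts$unit_id, rscu = rscu,
         family_sizes = stats::setNames(lengths(code$families),
                                        names(code$families)),
         code = code),
    class = "rscu_profile"
  )
}

#' Flag strong codon preference
#'
#' @param rscu Numeric RSCU value(s).
#' @param threshold Strong-preference cutoff (default 1.5, inclusive).
#' @return Logical vector.
#' @export
rscu_strong_preference <- function(rscu, threshold = 1.5) {
  !is.na(rscu) & rscu >= threshold
}

#' Wright's effective number of codons (ENC)
#'
#' Implements the Wright (1990) estimator with degeneracy classes derived
#' from the active genetic code rather than hard-coded standard-code
#' classes. For each synonymous family with k codons observed n >= 2 times
#' in total, the codon homozygosity is estimated as
#' `F = (n * sum(p^2) - 1) / (n - 1)`; family estimates are averaged within
#' each degeneracy class, and
#' `ENC = n_singleton_families + sum_k (N_k / Fbar_k)` where `N_k` is the
#' number of k-fold families in the code. A class with no usable family is
#' imputed as the mean of the adjacent class averages when both exist
#' (mirroring the classical treatment of an absent 3-fold class), otherwise
#' the estimate is flagged low-confidence and the class is dropped from the
#' sum (its families then do not contribute). Family estimates at or below
#' zero are floored at 1/k with a flag. The result is capped at the code's
#' sense-codon count (61 for the standard code, 62 for table 5).
#'
#' @param counts A `codon_counts` object with at least one degenerate
#'   family observed.
#' @return Numeric ENC with attributes `low_confidence` (logical),
#'   `imputed_classes` and `floored_families` (character vectors).
#' @export
compute_enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  code <- counts$code
  fam_sizes <- lengths(code$families)
  singletons <- sum(fam_sizes == 1L)
  classes <- sort(unique(fam_sizes[fam_sizes >= 2L]))

  fhat <- function(fam) {
    n <- sum(counts$counts[fam])
    if (n < 2L) return(NA_real_)
    p <- counts$counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }

  floored <- character(0)
  class_means <- stats::setNames(rep(NA_real_, length(classes)),
                                 as.character(classes))
  class_nfam <- stats::setNames(integer(length(classes)),
                                as.character(classes))
  any_obs <- FALSE
  for (k in classes) {
    fams <- names(fam_sizes)[fam_sizes == k]
    class_nfam[as.character(k)] <- length(fams)
    fs <- vapply(code$families[fams], fhat, numeric(1))
    if (any(!is.na(fs))) any_obs <- TRUE
    bad <- !is.na(fs) & fs <= 0
    if (any(bad)) {
      floored <- c(floored, fams[bad])
      fs[bad] <- 1 / k
    }
    if (any(!is.na(fs))) {
      class_means[as.character(k)] <- mean(fs, na.rm = TRUE)
    }
  }
  if (!any_obs) {
    stop("ENC undefined: no degenerate family observed with n >= 2",
         call. = FALSE)
  }

  imputed <- character(0)
  low_conf <- FALSE
  for (i in seq_along(classes)) {
    if (!is.na(class_means[i])) next
    lo <- if (i > 1L) class_means[i - 1L] else NA_real_
    hi <- if (i < length(classes)) class_means[i + 1L] else NA_real_
    if (!is.na(lo) && !is.na(hi)) {
      class_means[i] <- mean(c(lo, hi))
      imputed <- c(imputed, as.character(classes[i]))
    } else {
      low_conf <- TRUE
    }
  }

  usable <- !is.na(class_means)
  enc <- singletons + sum(class_nfam[usable] / class_means[usable])
  enc <- min(enc, code$enc_max)
  structure(enc, low_confidence = low_conf, imputed_classes = imputed,
            floored_families = floored)
}

#' Positional GC content
#'
#' GC fraction at each codon position over non-N bases, their first/second
#' position mean GC12 = (GC1 + GC2) / 2, and GC3s: the third-position GC
#' fraction restricted to synonymously variable codons (stop codons and
#' single-codon families of the active code excluded). Positions with no
#' countable base give `NA`.
#'
#' @param cds A `cds` object or sequence string.
#' @param table_id Translation table when `cds` is a bare string.
#' @return Named numeric: `gc1, gc2, gc3, gc12, gc3s`.
#' @export
positional_gc <- function(cds, table_id = NULL) {
  if (inherits(cds, "cds")) {
    seq <- cds$sequence
    table_id <- cds$table_id
  } else {
    seq <- as.character(cds)
    if (is.null(table_id)) table_id <- 1L
  }
  code <- load_genetic_code(table_id)
  codons <- split_codons(seq)
  if (!length(codons)) {
    return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
             gc12 = NA_real_, gc3s = NA_real_))
  }
  mat <- do.call(rbind, strsplit(codons, ""))
  pos_gc <- function(bases) {
    ok <- bases != "N"
    if (!any(ok)) return(NA_real_)
    mean(bases[ok] %in% c("G", "C"))
  }
  gc1 <- pos_gc(mat[, 1])
  gc2 <- pos_gc(mat[, 2])
  gc3 <- pos_gc(mat[, 3])
  deg <- degenerate_codons(code)
  third_s <- mat[codons %in% deg, 3]
  gc3s <- if (length(third_s)) pos_gc(third_s) else NA_real_
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2, gc3s = gc3s)
}

#' AT and GC strand skews
#'
#' `AT-skew = (A - T) / (A + T)` and `GC-skew = (G - C) / (G + C)` over the
#' coding strand; positive values mean enrichment of the first base of the
#' pair. A skew whose denominator is zero is reported as `NA`.
#'
#' @param x A `cds`, a sequence string, or a named base-count vector with
#'   entries `A,C,G,T`.
#' @return Named numeric: `at_skew, gc_skew`.
#' @export
compute_skews <- function(x) {
  if (inherits(x, "cds")) {
    bases <- strsplit(x$sequence, "")[[1]]
    cnt <- table(factor(bases, levels = c("A", "C", "G", "T")))
  } else if (is.character(x) && length(x) == 1L) {
    bases <- strsplit(toupper(x), "")[[1]]
    cnt <- table(factor(bases, levels = c("A", "C", "G", "T")))
  } else {
    stopifnot(all(c("A", "C", "G", "T") %in% names(x)))
    cnt <- x[c("A", "C", "G", "T")]
  }
  a <- as.numeric(cnt[["A"]]); t <- as.numeric(cnt[["T"]])
  g <- as.numeric(cnt[["G"]]); c_ <- as.numeric(cnt[["C"]])
  c(at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_)
}

#' Relative adaptiveness weights from a reference codon-count table
#'
#' Within each synonymous family, `w = count / max(count)` after replacing
#' zero reference counts by a 0.5 pseudo-count (the classical smoothing
#' convention), so every weight lies in (0, 1] and the most frequent codon
#' of each family has weight 1. Single-codon families receive w = 1 but are
#' excluded from CAI computation.
#'
#' @param pooled A `codon_counts` object, typically the pooled counts of a
#'   species' 13 mitochondrial protein-coding genes (self-referenced mode).
#' @param reference_desc Provenance string stored with the weights.
#' @return An `adaptiveness_weights` object: list with `weights` (named
#'   numeric over sense codons) and `reference_desc`.
#' @export
reference_weights <- function(pooled, reference_desc = "self-referenced") {
  stopifnot(inherits(pooled, "codon_counts"))
  if (pooled$total_codons == 0L) {
    stop("empty reference: no sense codons observed", call. = FALSE)
  }
  code <- pooled$code
  w <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                       code$sense_codons)
  for (fam in code$families) {
    cnts <- as.numeric(pooled$counts[fam])
    mx <- max(cnts)
    if (mx == 0) {
      # family entirely unobserved in the reference: uninformative weights
      w[fam] <- 1
      next
    }
    cnts[cnts == 0] <- 0.5
    w[fam] <- cnts / mx
  }
  structure(list(weights = w, reference_desc = reference_desc, code = code),
            class = "adaptiveness_weights")
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights of a gene's codons,
#' `CAI = exp(mean(log w))`, computed over codons of degenerate families
#' only (stop codons and single-codon families excluded). 1 means the gene
#' exclusively uses each family's most frequent reference codon.
#'
#' @param gene_counts A `codon_counts` object for the gene.
#' @param weights An `adaptiveness_weights` object on the same code.
#' @return CAI in (0, 1], or `NA` when the gene has no codon in a
#'   degenerate family.
#' @export
compute_cai <- function(gene_counts, weights) {
  stopifnot(inherits(gene_counts, "codon_counts"),
            inherits(weights, "adaptiveness_weights"))
  if (gene_counts$code$table_id != weights$code$table_id) {
    stop("gene and weights use different genetic codes", call. = FALSE)
  }
  deg <- degenerate_codons(gene_counts$code)
  cnts <- gene_counts$counts[deg]
  L <- sum(cnts)
  if (L == 0L) return(NA_real_)
  exp(sum(cnts * log(weights$weights[deg])) / L)
}

#' Per-unit codon-usage metrics table
#'
#' Computes the full metric set (ENC, positional GC, skews, AT/GC content,
#' optional CAI) for one coding sequence.
#'
#' @param cds A `cds` object.
#' @param weights Optional `adaptiveness_weights` for CAI.
#' @return One-row data.frame.
#' @export
gene_metrics <- function(cds, weights = NULL) {
  cc <- count_codons(cds)
  gc <- positional_gc(cds)
  sk <- compute_skews(cds)
  bases <- strsplit(gsub("N", "", cds$sequence), "")[[1]]
  atc <- if (length(bases)) mean(bases %in% c("A", "T")) else NA_real_
  enc <- tryCatch(as.numeric(compute_enc(cc)), error = function(e) NA_real_)
  cai <- if (!is.null(weights)) compute_cai(cc, weights) else NA_real_
  data.frame(
    species_id = cds$species_id, compartment = cds$compartment,
    gene = cds$gene, n_codons = cc$total_codons,
    enc = enc, gc1 = gc[["gc1"]], gc2 = gc[["gc2"]], gc3 = gc[["gc3"]],
    gc12 = gc[["gc12"]], gc3s = gc[["gc3s"]],
    at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
    at_content = atc, gc_content = 1 - atc, cai = cai,
    stringsAsFactors = FALSE
  )
}
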