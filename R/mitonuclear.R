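# Per-species mitonuclear coadaptation statistics: correlation of RSCU
# vectors across a shared codon set, a normalized mutual-information
# dependence statistic |M| in [0, 1], and the coadapted / intermediate /
# decoupled classification.

#' Correlation between mitochondrial and nuclear RSCU vectors
#'
#' Pearson r and Spearman rho over paired codon RSCU values on a shared
#' codon set (default: the 59 degenerate standard-code sense codons,
#' excluding ATG, TGG and stops). Codons undefined in either profile
#' (unobserved family) are pairwise-dropped and counted.
#'
#' @param rscu_mito,rscu_nuc `rscu_profile` objects or named RSCU vectors.
#' @param codons Shared codon set (default `codon_set("shared59")`).
#' @return List with `r_pearson`, `rho_spearman`, `n_codons_used`,
#'   `n_dropped`.
#' @export
compartment_correlation <- function(rscu_mito, rscu_nuc,
                                    codons = codon_set("shared59")) {
  v1 <- if (inherits(rscu_mito, "rscu_profile")) rscu_mito$rscu else rscu_mito
  v2 <- if (inherits(rscu_nuc, "rscu_profile")) rscu_nuc$rscu else rscu_nuc
  missing1 <- setdiff(codons, names(v1))
  missing2 <- setdiff(codons, names(v2))
  x <- stats::setNames(rep(NA_real_, length(codons)), codons)
  y <- x
  x[setdiff(codons, missing1)] <- v1[setdiff(codons, missing1)]
  y[setdiff(codons, missing2)] <- v2[setdiff(codons, missing2)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L) {
    stop("insufficient overlap: fewer than 10 shared codons with defined RSCU",
         call. = FALSE)
  }
  list(
    r_pearson = stats::cor(x[ok], y[ok], method = "pearson"),
    rho_spearman = stats::cor(x[ok], y[ok], method = "spearman"),
    n_codons_used = sum(ok),
    n_dropped = sum(!ok)
  )
}

# Equal-frequency binning by rank; ties broken deterministically by codon
# label order so the statistic is a pure function of its inputs.
equal_frequency_bins <- function(v, bins) {
  n <- length(v)
  rank_ix <- order(v, names(v))
  r <- integer(n)
  r[rank_ix] <- seq_len(n)
  as.integer(floor((r - 1) * bins / n) + 1L)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between compartment RSCU vectors
#'
#' Discretizes each vector into equal-frequency bins over the shared
#' codons (rank-based, ties broken by codon label order), computes the
#' plug-in mutual information of the joint bin histogram, and normalizes
#' by the smaller marginal entropy: `|M| = MI / min(H_mito, H_nuc)` with
#' 0/0 defined as 0. Bounded in [0, 1]; equals 1 when one vector is a
#' strictly monotone transform of the other (in particular for identical
#' vectors), and is invariant to monotone transforms of either input.
#'
#' @param rscu_mito,rscu_nuc `rscu_profile` objects or named RSCU vectors.
#' @param bins Number of equal-frequency bins (default 4).
#' @param codons Shared codon set (default `codon_set("shared59")`).
#' @return `m_norm` in [0, 1] with attribute `degenerate` flagging
#'   all-equal input.
#' @export
normalized_mutual_information <- function(rscu_mito, rscu_nuc, bins = 4L,
                                          codons = codon_set("shared59")) {
  v1 <- if (inherits(rscu_mito, "rscu_profile")) rscu_mito$rscu else rscu_mito
  v2 <- if (inherits(rscu_nuc, "rscu_profile")) rscu_nuc$rscu else rscu_nuc
  x <- v1[intersect(codons, names(v1))]
  y <- v2[intersect(codons, names(v2))]
  shared <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  if (length(shared) < 10L) {
    stop("insufficient overlap: fewer than 10 shared codons with defined RSCU",
         call. = FALSE)
  }
  x <- x[shared]
  y <- y[shared]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  bx <- equal_frequency_bins(x, bins)
  by <- equal_frequency_bins(y, bins)
  joint <- table(bx, by) / length(shared)
  hx <- entropy_nat(rowSums(joint))
  hy <- entropy_nat(colSums(joint))
  mi <- hx + hy - entropy_nat(as.vector(joint))
  denom <- min(hx, hy)
  m <- if (denom == 0) 0 else mi / denom
  structure(max(0, min(1, m)), degenerate = FALSE)
}

#' Classify mitonuclear coadaptation from the RSCU correlation
#'
#' Coadapted when `r >= r_coadapt` (default 0.7), decoupled when
#' `r < r_decouple` (default 0.2, an operationalization of "near zero"),
#' intermediate otherwise. |M| is reported alongside but does not enter
#' the default rule.
#'
#' @param r Pearson correlation.
#' @param m_norm Optional |M| (carried through, unused by the rule).
#' @param thresholds Named numeric `c(r_coadapt = 0.7, r_decouple = 0.2)`.
#' @return `"coadapted"`, `"intermediate"` or `"decoupled"`.
#' @export
classify_coadaptation <- function(r, m_norm = NA_real_,
                                  thresholds = c(r_coadapt = 0.7,
                                                 r_decouple = 0.2)) {
  stopifnot(!is.na(r))
  if (r >= thresholds[["r_coadapt"]]) return("coadapted")
  if (r < thresholds[["r_decouple"]]) return("decoupled")
  "intermediate"
}

#' Per-species coadaptation table
#'
#' Computes r, rho, |M| and the class label for each species from paired
#' mitochondrial and nuclear RSCU profiles.
#'
#' @param mito_profiles,nuc_profiles Named lists of `rscu_profile` keyed by
#'   species id (names must match).
#' @param codons Shared codon set.
#' @param bins Bins for the mutual-information statistic.
#' @param thresholds Classification thresholds.
#' @return Data.frame: species_id, r_pearson, rho_spearman, m_norm,
#'   n_codons_used, class_label.
#' @export
coadaptation_table <- function(mito_profiles, nuc_profiles,
                               codons = codon_set("shared59"), bins = 4L,
                               thresholds = c(r_coadapt = 0.7,
                                              r_decouple = 0.2)) {
  species <- intersect(names(mito_profiles), names(nuc_profiles))
  if (!length(species)) stop("no species shared between compartments",
                             call. = FALSE)
  rows <- lapply(species, function(sp) {
    cc <- compartment_correlation(mito_profiles[[sp]], nuc_profiles[[sp]],
                                  codons = codons)
    m <- normalized_mutual_information(mito_profiles[[sp]],
                                       nuc_profiles[[sp]],
                                       bins = bins, codons = codons)
    data.frame(species_id = sp, r_pearson = cc$r_pearson,
               rho_spearman = cc$rho_spearman, m_norm = as.numeric(m),
               n_codons_used = cc$n_codons_used,
               class_label = classify_coadaptation(cc$r_pearson, m,
                                                   thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
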