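# Multivariate structure of codon usage: species-by-codon RSCU matrix
# assembly, column z-scoring, correlation-matrix PCA with loading
# diagnostics, PERMANOVA on Euclidean distances (seeded random or
# exhaustive permutations), dispersion homogeneity, and hierarchical
# clustering for heat-map row ordering.

#' Assemble a units-by-codon RSCU matrix
#'
#' Rows are units (species or species-compartment), columns a fixed,
#' amino-acid-grouped codon set. `"standard_60"` uses the standard-code
#' sense codons minus ATG (60 columns) regardless of the profiles' table;
#' `"code_aware"` uses the degenerate sense codons of the profiles' own
#' code (62 columns under table 5, where the TGA/TGG Trp family is
#' degenerate). RSCU entries of families unobserved in a unit are imputed
#' as 0 (the unit genuinely uses none of those codons) and the imputation
#' count is recorded.
#'
#' @param profiles List of `rscu_profile` objects.
#' @param codon_set_mode `"standard_60"` or `"code_aware"`.
#' @return An `rscu_matrix`: list with `values` (numeric matrix), `scaled`
#'   (FALSE), `codon_set_mode`, `n_imputed`, `dropped_columns`.
#' @export
assemble_matrix <- function(profiles,
                            codon_set_mode = c("standard_60",
                                               "code_aware")) {
  codon_set_mode <- match.arg(codon_set_mode)
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  cols <- if (codon_set_mode == "standard_60") {
    codon_set("standard60")
  } else {
    codon_set("code_aware", profiles[[1]]$code)
  }
  vals <- t(vapply(profiles, function(p) {
    v <- rep(NA_real_, length(cols))
    hit <- cols %in% names(p$rscu)
    v[hit] <- p$rscu[cols[hit]]
    v
  }, numeric(length(cols))))
  rownames(vals) <- vapply(profiles, `[[`, character(1), "unit_id")
  colnames(vals) <- cols
  n_imputed <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  structure(
    list(values = vals, scaled = FALSE, codon_set_mode = codon_set_mode,
         n_imputed = n_imputed, dropped_columns = character(0)),
    class = "rscu_matrix"
  )
}

#' Z-score the columns of an RSCU matrix
#'
#' Centers and scales each codon column (sample standard deviation).
#' Zero-variance columns are dropped and listed. Re-scaling an already
#' scaled matrix leaves values unchanged.
#'
#' @param m An `rscu_matrix` with >= 2 rows.
#' @return The matrix with standardized columns, `scaled = TRUE`, and
#'   `dropped_columns` recording removed codons.
#' @export
zscore_columns <- function(m) {
  stopifnot(inherits(m, "rscu_matrix"), nrow(m$values) >= 2L)
  sds <- apply(m$values, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all columns have zero variance", call. = FALSE)
  dropped <- colnames(m$values)[!keep]
  vals <- scale(m$values[, keep, drop = FALSE])
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  m$values <- vals
  m$scaled <- TRUE
  m$dropped_columns <- c(m$dropped_columns, dropped)
  m
}

#' PCA of a scaled RSCU matrix
#'
#' Singular value decomposition of the column-centered data (on z-scored
#' input this is correlation-matrix PCA). Loadings follow a deterministic
#' sign convention: within each component the loading of largest magnitude
#' is non-negative. Codon contributions per component are
#' `100 * loading^2 / sum(loading^2)`; cos2 is the squared cosine of each
#' row (and codon) against each component.
#'
#' @param m A scaled `rscu_matrix` (or any `rscu_matrix`; scaling state is
#'   the caller's responsibility) with >= 2 rows.
#' @return An `ordination` list: `scores`, `loadings`,
#'   `explained_variance` (percent, non-increasing), `contrib`,
#'   `cos2_rows`, `cos2_codons`.
#' @export
pca_rscu <- function(m) {
  stopifnot(inherits(m, "rscu_matrix"), nrow(m$values) >= 2L)
  x <- m$values
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry per PC non-negative
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- 100 * p$sdev^2 / sum(p$sdev^2)
  contrib <- sweep(p$rotation^2, 2, colSums(p$rotation^2), "/") * 100
  row_sq <- p$x^2
  cos2_rows <- row_sq / rowSums(row_sq)
  load_sq <- sweep(p$rotation^2, 2, p$sdev^2, "*")
  cos2_codons <- load_sq / rowSums(load_sq)
  structure(
    list(scores = p$x, loadings = p$rotation,
         explained_variance = ev, contrib = contrib,
         cos2_rows = cos2_rows, cos2_codons = cos2_codons,
         sdev = p$sdev, center = p$center),
    class = "ordination"
  )
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    if (length(ix) > 1L) {
      sub <- d2[ix, ix]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
  }
  ss_between <- ss_total - ss_within
  g <- length(unique(groups))
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(f = f, r2 = ss_between / ss_total)
}

#' PERMANOVA on Euclidean distances
#'
#' Partitions the squared Euclidean distance matrix into between- and
#' within-group sums of squares, reports the pseudo-F
#' `(SS_B / (g - 1)) / (SS_W / (N - g))` and `R^2 = SS_B / SS_total`, and
#' obtains the permutation p-value `(#{F_perm >= F_obs} + 1) /
#' (permutations + 1)` under free random permutation of row labels. With
#' `permutations = "exhaustive"` all distinct label assignments are
#' enumerated and `p = #{F_perm >= F_obs} / n_assignments` (the identity
#' assignment included). Invariant to label order and to adding a constant
#' to all coordinates.
#'
#' @param x Numeric matrix (rows = units) or an `rscu_matrix`.
#' @param labels Grouping vector, length `nrow(x)`; every group needs >= 2
#'   members.
#' @param permutations Integer count of random permutations (default
#'   10000), or `"exhaustive"`.
#' @param seed RNG seed for random permutations.
#' @return A `permanova_result` list: `pseudo_f`, `r_squared`, `p_value`,
#'   `permutations`, `seed`, `exhaustive`.
#' @export
permanova <- function(x, labels, permutations = 10000L, seed = 12345L) {
  if (inherits(x, "rscu_matrix")) x <- x$values
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("every group needs >= 2 members", call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  obs <- permanova_f(d2, labels)

  exhaustive <- identical(permutations, "exhaustive")
  if (exhaustive) {
    perms <- unique_label_assignments(labels)
    fs <- vapply(perms, function(l) permanova_f(d2, l)[["f"]], numeric(1))
    p <- mean(fs >= obs[["f"]] - 1e-12)
    n_perm <- length(perms)
  } else {
    n_perm <- as.integer(permutations)
    old <- .Random.seed_safe_get()
    on.exit(.Random.seed_safe_restore(old), add = TRUE)
    set.seed(seed)
    count <- 0L
    for (i in seq_len(n_perm)) {
      f_i <- permanova_f(d2, labels[sample.int(length(labels))])[["f"]]
      if (f_i >= obs[["f"]] - 1e-12) count <- count + 1L
    }
    p <- (count + 1) / (n_perm + 1)
  }
  structure(
    list(pseudo_f = obs[["f"]], r_squared = obs[["r2"]], p_value = p,
         permutations = n_perm, seed = if (exhaustive) NA_integer_ else seed,
         exhaustive = exhaustive),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (Euclidean): pseudo-F %.4f, R^2 %.4f, p %.5g (%s%d perms)\n",
    x$pseudo_f, x$r_squared, x$p_value,
    if (x$exhaustive) "exhaustive, " else "", x$permutations))
  invisible(x)
}

# All distinct assignments of the multiset of labels to positions.
unique_label_assignments <- function(labels) {
  n <- length(labels)
  uniq <- sort(unique(labels))
  assignments <- list(character(0))
  remaining <- list(table(factor(labels, levels = uniq)))
  for (pos in seq_len(n)) {
    new_a <- list(); new_r <- list()
    for (k in seq_along(assignments)) {
      counts <- remaining[[k]]
      for (u in uniq[counts[uniq] > 0]) {
        cnt2 <- counts
        cnt2[u] <- cnt2[u] - 1L
        new_a[[length(new_a) + 1L]] <- c(assignments[[k]], u)
        new_r[[length(new_r) + 1L]] <- cnt2
      }
    }
    assignments <- new_a
    remaining <- new_r
  }
  assignments
}

#' Homogeneity of multivariate dispersion
#'
#' Permutation test on group dispersions (distances of rows to their group
#' centroid in principal-coordinate space), the standard companion check
#' for PERMANOVA. Wraps `vegan::betadisper` + `vegan::permutest`.
#'
#' @param x Numeric matrix or `rscu_matrix`.
#' @param labels Grouping vector.
#' @param permutations Permutation count.
#' @param seed RNG seed.
#' @return List with `p_value`, `f`, `permutations`, `seed`.
#' @export
dispersion_test <- function(x, labels, permutations = 999L, seed = 12345L) {
  if (inherits(x, "rscu_matrix")) x <- x$values
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("every group needs >= 2 members", call. = FALSE)
  }
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  set.seed(seed)
  bd <- vegan::betadisper(stats::dist(x), group = factor(labels))
  pt <- vegan::permutest(bd, permutations = permutations)
  list(p_value = pt$tab[1, "Pr(>F)"], f = pt$tab[1, "F"],
       permutations = as.integer(permutations), seed = as.integer(seed))
}

#' Hierarchical leaf ordering for heat maps
#'
#' Complete-linkage agglomeration on Euclidean distances with
#' deterministic tie-breaking by row index (the behaviour of
#' `stats::hclust` given a fixed input order).
#'
#' @param x Numeric matrix or `rscu_matrix` with >= 2 rows.
#' @return List with `order` (leaf indices), `labels` (leaf row names in
#'   display order), and `hclust` (the linkage record).
#' @export
hierarchical_order <- function(x) {
  if (inherits(x, "rscu_matrix")) x <- x$values
  stopifnot(nrow(x) >= 2L)
  hc <- stats::hclust(stats::dist(x), method = "complete")
  list(order = hc$order,
       labels = if (!is.null(rownames(x))) rownames(x)[hc$order] else hc$order,
       hclust = hc)
}
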