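# Selection-versus-mutation diagnostics: ENC-GC3 deviation from Wright's
# neutral expectation, the GC12-on-GC3 neutrality regression with a
# gene-within-species bootstrap, and order-level Kruskal-Wallis tests with
# Benjamini-Hochberg correction.

#' Wright's expected ENC under pure compositional bias
#'
#' `ENC_exp = 2 + GC3 + 29 / (GC3^2 + (1 - GC3)^2)`: the effective number
#' of codons expected when codon usage is determined solely by
#' third-position GC content. Genes falling below this curve show codon
#' bias stronger than composition alone predicts.
#'
#' @param gc3 GC3 value(s) in \[0, 1\].
#' @return Expected ENC, same length as `gc3`.
#' @export
enc_expected <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 < 0 | gc3 > 1)) {
    stop("gc3 must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' ENC deviation from the neutral expectation
#'
#' `D = ENC_exp(GC3s) - ENC` per unit; positive D means the unit sits below
#' the curve (bias stronger than predicted). Summaries aggregate mean D per
#' species and then per order, plus the fraction of units below the curve.
#'
#' @param points Data.frame with columns `enc`, `gc3s`, `species_id`,
#'   `order_label` (extra columns pass through).
#' @return List with `points` (input plus column `d`), `by_species`,
#'   `by_order` (mean/sd of per-species means), and `fraction_below`.
#' @export
enc_deviation <- function(points) {
  stopifnot(nrow(points) > 0,
            all(c("enc", "gc3s", "species_id", "order_label") %in%
                  names(points)))
  points$d <- enc_expected(points$gc3s) - points$enc
  by_sp <- stats::aggregate(d ~ species_id + order_label, points, mean)
  names(by_sp)[names(by_sp) == "d"] <- "mean_d"
  by_ord <- do.call(rbind, lapply(split(by_sp, by_sp$order_label), function(g) {
    data.frame(order_label = g$order_label[1], mean_d = mean(g$mean_d),
               sd_d = stats::sd(g$mean_d), n_species = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(by_ord) <- NULL
  list(points = points, by_species = by_sp, by_order = by_ord,
       fraction_below = mean(points$d > 0))
}

#' GC12-on-GC3 neutrality regression
#'
#' Ordinary least squares of GC12 on GC3. A slope near 1 indicates
#' composition driven by mutation pressure shared across codon positions; a
#' slope much below 1 indicates selective constraint at positions 1-2
#' uncoupling them from third-position variation.
#'
#' @param points Data.frame with columns `gc12` and `gc3` (rows with `NA`
#'   dropped).
#' @return A `neutrality_fit` list: `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
neutrality_fit <- function(points) {
  pts <- points[stats::complete.cases(points[, c("gc12", "gc3")]), ]
  if (nrow(pts) < 3L) stop("need >= 3 complete points", call. = FALSE)
  if (stats::sd(pts$gc3) == 0) {
    stop("degenerate fit: zero variance in gc3", call. = FALSE)
  }
  fit <- stats::lm(gc12 ~ gc3, data = pts)
  ss_tot <- sum((pts$gc12 - mean(pts$gc12))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = nrow(pts)),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("GC12 ~ GC3: slope %.4f, intercept %.4f, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  if (!is.null(x$slope_ci)) {
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f] (B = %d, seed %d)\n",
                x$slope_ci[1], x$slope_ci[2], x$bootstrap_B, x$seed))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the neutrality slope
#'
#' Nonparametric bootstrap that resamples genes with replacement within
#' each species, refits the OLS regression of GC12 on GC3 per replicate,
#' and takes the 2.5/97.5 percentiles of the replicate slopes. With
#' `unit = "species"` each replicate's points are the codon-weighted
#' species means of the resampled genes (the species-level concatenation
#' summary); with `unit = "gene"` the resampled gene points themselves are
#' refit.
#'
#' @param points Data.frame with columns `species_id`, `gc12`, `gc3` and,
#'   for species-level summaries, `n_codons`.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed RNG seed (default 12345).
#' @param unit `"gene"` or `"species"` regression unit.
#' @return A `neutrality_fit` for the observed points augmented with
#'   `slope_ci`, `bootstrap_B`, `seed`, and `n_degenerate` (replicates
#'   skipped for zero GC3 variance).
#' @export
bootstrap_slope <- function(points, B = 10000L, seed = 12345L,
                            unit = c("gene", "species")) {
  unit <- match.arg(unit)
  stopifnot(all(c("species_id", "gc12", "gc3") %in% names(points)))
  if (B < 100L) warning("B < 100 gives unstable percentile CIs")
  pts <- points[stats::complete.cases(points[, c("gc12", "gc3")]), ]
  by_sp <- split(seq_len(nrow(pts)), pts$species_id)
  if (length(by_sp) < 2L) stop("need >= 2 species", call. = FALSE)

  species_points <- function(df) {
    wcol <- if ("n_codons" %in% names(df)) df$n_codons else rep(1, nrow(df))
    agg <- lapply(split(df, df$species_id), function(g) {
      w <- if ("n_codons" %in% names(g)) g$n_codons else rep(1, nrow(g))
      data.frame(gc12 = stats::weighted.mean(g$gc12, w),
                 gc3 = stats::weighted.mean(g$gc3, w))
    })
    do.call(rbind, agg)
  }
  observed <- if (unit == "species") {
    neutrality_fit(species_points(pts))
  } else {
    neutrality_fit(pts)
  }

  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  set.seed(seed)
  slopes <- rep(NA_real_, B)
  degenerate <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(by_sp, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    rep_pts <- pts[idx, ]
    fit_pts <- if (unit == "species") species_points(rep_pts) else rep_pts
    if (nrow(fit_pts) < 3L || stats::sd(fit_pts$gc3) == 0) {
      degenerate <- degenerate + 1L
      next
    }
    xv <- fit_pts$gc3
    yv <- fit_pts$gc12
    slopes[b] <- stats::cov(xv, yv) / stats::var(xv)
  }
  ci <- stats::quantile(slopes, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  observed$slope_ci <- ci
  observed$bootstrap_B <- as.integer(B)
  observed$seed <- as.integer(seed)
  observed$n_degenerate <- degenerate
  observed
}

# Preserve the caller's RNG state around seeded internals.
.Random.seed_safe_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_safe_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Order-level Kruskal-Wallis tests with BH correction
#'
#' Runs a Kruskal-Wallis rank-sum test per metric across taxonomic orders
#' and adjusts the p-values with the Benjamini-Hochberg step-up procedure
#' across the metric family tested in this one invocation (the family is
#' reported so it cannot drift silently).
#'
#' @param data Data.frame of per-unit metrics.
#' @param metrics Character vector of metric column names to test.
#' @param group Grouping column name (default `"order_label"`).
#' @return Data.frame: metric, statistic (KW H), df, p_raw, p_adjusted,
#'   n_groups, family_size.
#' @export
order_level_test <- function(data, metrics, group = "order_label") {
  stopifnot(group %in% names(data), all(metrics %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  tab <- table(g)
  if (any(tab < 2L)) stop("every group needs >= 2 observations", call. = FALSE)
  rows <- lapply(metrics, function(m) {
    ok <- !is.na(data[[m]])
    kt <- stats::kruskal.test(data[[m]][ok], g[ok])
    data.frame(metric = m, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p_raw = kt$p.value,
               n_groups = nlevels(droplevels(g[ok])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$family_size <- length(metrics)
  out
}
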