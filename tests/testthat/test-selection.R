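test_that("Wright's expected-ENC curve matches hand values and its symmetry", {
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0.5), 60.5)
  expect_error(enc_expected(1.2), "0, 1")
  # symmetric about 0.5 up to the linear term
  xs <- seq(0.05, 0.95, 0.05)
  expect_equal(enc_expected(xs) - xs, enc_expected(1 - xs) - (1 - xs))
})

test_that("ENC deviation D and its summaries behave as defined", {
  pts <- data.frame(
    species_id = c("a", "a", "b", "b"),
    order_label = c("O1", "O1", "O2", "O2"),
    gene = paste0("g", 1:4),
    enc = c(enc_expected(0.3), 30, 40, 50),
    gc3s = c(0.3, 0.5, 0.5, 0.5))
  dev <- enc_deviation(pts)
  expect_equal(dev$points$d[1], 0)
  expect_equal(dev$points$d[2], enc_expected(0.5) - 30)  # 30.5
  expect_equal(dev$by_species$mean_d[dev$by_species$species_id == "b"],
               mean(c(60.5 - 40, 60.5 - 50)))
  expect_equal(dev$fraction_below, 3 / 4)
})

test_that("neutrality regression recovers exact and degenerate cases", {
  pts <- data.frame(gc3 = c(0.2, 0.4, 0.6, 0.8),
                    gc12 = c(0.2, 0.4, 0.6, 0.8))
  fit <- neutrality_fit(pts)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)

  flat <- data.frame(gc3 = c(0.2, 0.4, 0.6), gc12 = c(0.5, 0.5, 0.5))
  expect_equal(neutrality_fit(flat)$slope, 0)

  expect_error(neutrality_fit(data.frame(gc3 = c(0.5, 0.5, 0.5),
                                         gc12 = c(0.1, 0.2, 0.3))),
               "degenerate")
  expect_error(neutrality_fit(pts[1:2, ]), ">= 3")
})

test_that("bootstrap slope CI is deterministic, ordered and collapses when collinear", {
  set.seed(33)
  pts <- data.frame(
    species_id = rep(c("a", "b", "c"), each = 10),
    gc3 = runif(30, 0.2, 0.8))
  pts$gc12 <- 0.1 + 0.9 * pts$gc3 + rnorm(30, 0, 0.01)

  f1 <- bootstrap_slope(pts, B = 200, seed = 7)
  f2 <- bootstrap_slope(pts, B = 200, seed = 7)
  expect_identical(f1$slope_ci, f2$slope_ci)
  expect_lte(f1$slope_ci[1], f1$slope)
  expect_gte(f1$slope_ci[2], f1$slope)

  # perfectly collinear points: every replicate refits the same line
  col <- data.frame(species_id = rep(c("a", "b"), each = 5),
                    gc3 = rep(seq(0.1, 0.9, 0.2), 2))
  col$gc12 <- col$gc3
  fc <- bootstrap_slope(col, B = 200, seed = 1)
  expect_equal(unname(fc$slope_ci), c(1, 1))

  expect_warning(bootstrap_slope(pts, B = 50, seed = 1), "B < 100")
})

test_that("bootstrap respects species grouping: row order does not matter", {
  set.seed(44)
  pts <- data.frame(
    species_id = rep(c("a", "b", "c", "d"), each = 8),
    gc3 = runif(32, 0.2, 0.8))
  pts$gc12 <- 0.05 + 0.8 * pts$gc3 + rnorm(32, 0, 0.02)
  shuffled <- pts[sample(nrow(pts)), ]
  f1 <- bootstrap_slope(pts, B = 300, seed = 5)
  f2 <- bootstrap_slope(shuffled, B = 300, seed = 5)
  # same observed fit; CI distributions drawn from the same scheme
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$slope_ci, f2$slope_ci, tolerance = 0.05)
})

test_that("neutral cohorts recover slope near 1; pinned GC12 drives slope to 0", {
  set.seed(2025)
  gcs <- runif(8, 0.2, 0.8)
  # free composition: all positions follow the species GC propensity
  free_pts <- do.call(rbind, lapply(seq_along(gcs), function(i) {
    m <- compartment_model(gc_bias = gcs[i])
    do.call(rbind, lapply(1:6, function(k) {
      gc <- positional_gc(generate_gene(m, 300, composition = "free"))
      data.frame(species_id = paste0("s", i), gc12 = gc[["gc12"]],
                 gc3 = gc[["gc3"]])
    }))
  }))
  slope_free <- neutrality_fit(free_pts)$slope
  expect_gt(slope_free, 0.85)
  expect_lt(slope_free, 1.1)

  # fixed amino-acid composition pins positions 1-2: slope collapses
  fixed_pts <- do.call(rbind, lapply(seq_along(gcs), function(i) {
    m <- compartment_model(gc_bias = gcs[i])
    do.call(rbind, lapply(1:6, function(k) {
      gc <- positional_gc(generate_gene(m, 300, composition = "fixed"))
      data.frame(species_id = paste0("s", i), gc12 = gc[["gc12"]],
                 gc3 = gc[["gc3"]])
    }))
  }))
  slope_fixed <- neutrality_fit(fixed_pts)$slope
  expect_lt(slope_fixed, 0.3)
  expect_lt(slope_fixed, slope_free)
})

test_that("growing constraint on positions 1-2 lowers the slope monotonically", {
  # selective constraint at positions 1-2 = amino-acid-level constraint:
  # model it as an increasing fraction of composition-pinned sites spliced
  # into an otherwise free (mutation-tracking) gene; the neutrality slope
  # must fall monotonically from near 1 toward 0
  set.seed(77)
  gcs <- runif(10, 0.2, 0.8)
  slope_at <- function(q_pinned) {
    pts <- do.call(rbind, lapply(seq_along(gcs), function(i) {
      m <- compartment_model(gc_bias = gcs[i])
      do.call(rbind, lapply(1:5, function(k) {
        n_pin <- round(300 * q_pinned)
        parts <- c(
          if (n_pin < 300) {
            generate_gene(m, 300 - n_pin, composition = "free")$sequence
          },
          if (n_pin > 0) {
            generate_gene(m, n_pin, composition = "fixed")$sequence
          })
        gc <- positional_gc(paste(parts, collapse = ""))
        data.frame(gc12 = gc[["gc12"]], gc3 = gc[["gc3"]])
      }))
    }))
    neutrality_fit(pts)$slope
  }
  slopes <- vapply(c(0, 0.5, 0.9), slope_at, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_lt(slopes[3], 0.5 * slopes[1])
  expect_lt(slopes[2], 1)
})

test_that("Kruskal-Wallis order tests and BH adjustment are wired correctly", {
  # BH on p = (0.01, 0.02, 0.04) with m = 3 -> (0.03, 0.03, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))

  set.seed(88)
  d <- data.frame(order_label = rep(c("O1", "O2", "O3"), each = 20),
                  enc = rnorm(60, 45, 3), gc3s = runif(60))
  d$enc[d$order_label == "O3"] <- d$enc[d$order_label == "O3"] + 15  # 5 SD
  res <- order_level_test(d, metrics = c("enc", "gc3s"))
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_lt(res$p_adjusted[res$metric == "enc"], 0.05)
  expect_equal(unique(res$family_size), 2)
  # cross-check H statistic against a direct kruskal.test call
  kt <- stats::kruskal.test(enc ~ order_label, data = d)
  expect_equal(res$statistic[res$metric == "enc"], unname(kt$statistic))

  expect_error(order_level_test(d[d$order_label == "O1", ], "enc"),
               ">= 2 groups")
})

test_that("shifted groups are detected while identical groups mostly are not", {
  set.seed(99)
  null_p <- replicate(60, {
    d <- data.frame(order_label = rep(c("A", "B", "C"), each = 10),
                    m = rnorm(30))
    order_level_test(d, "m")$p_adjusted
  })
  expect_gt(mean(null_p > 0.05), 0.80)
  power_p <- replicate(20, {
    d <- data.frame(order_label = rep(c("A", "B"), each = 20), m = rnorm(40))
    d$m[d$order_label == "B"] <- d$m[d$order_label == "B"] + 5
    order_level_test(d, "m")$p_adjusted
  })
  expect_true(all(power_p < 0.05))
})

test_that("bootstrap CIs cover the cohort's exact structural slope", {
  # known truth per cohort: expected GC12/GC3 of each species computed
  # exactly from the sense-codon distribution; the structural slope is the
  # OLS fit through those exact points. The gene-within-species bootstrap
  # CI (species-level unit) should cover it in >= 90% of cohorts.
  exact_gc <- function(gc_bias) {
    m <- compartment_model(gc_bias = gc_bias, table_id = 1L)
    p <- mitocub:::sense_codon_distribution(m)
    b <- do.call(rbind, strsplit(names(p), ""))
    gcpos <- vapply(1:3, function(k) sum(p[b[, k] %in% c("G", "C")]),
                    numeric(1))
    c(gc12 = mean(gcpos[1:2]), gc3 = gcpos[3])
  }
  set.seed(314)
  covered <- vapply(1:15, function(rep) {
    gcs <- runif(10, 0.2, 0.8)
    truth <- as.data.frame(t(vapply(gcs, exact_gc, numeric(2))))
    slope_true <- neutrality_fit(truth)$slope
    pts <- do.call(rbind, lapply(seq_along(gcs), function(i) {
      m <- compartment_model(gc_bias = gcs[i], table_id = 1L)
      do.call(rbind, lapply(1:20, function(k) {
        gc <- positional_gc(generate_gene(m, 300, composition = "free"))
        data.frame(species_id = paste0("s", i), gc12 = gc[["gc12"]],
                   gc3 = gc[["gc3"]], n_codons = 301)
      }))
    }))
    fit <- bootstrap_slope(pts, B = 400, seed = rep, unit = "species")
    fit$slope_ci[1] <= slope_true && slope_true <= fit$slope_ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
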