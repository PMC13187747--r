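# End-to-end orchestration: configuration, stage sequencing (QC -> codon
# quantification -> RSCU -> clustering/PCA -> skews -> ENC-GC3/neutrality ->
# CAI -> statistics -> coadaptation), output bundling, and the text report.

#' Pipeline configuration
#'
#' Either `input_dir` (a cohort directory holding `metadata.tsv` with
#' columns species_id, order_label, mito_path, nuclear_path) or `cohort`
#' (a [cohort_spec()] simulated in memory) must be supplied.
#'
#' @param input_dir Directory with on-disk inputs, or `NULL`.
#' @param cohort A `cohort_spec`, or `NULL`.
#' @param qc A [qc_policy()].
#' @param codon_set_mode `"standard_60"` or `"code_aware"` for the RSCU
#'   matrices.
#' @param permutations PERMANOVA permutations (0 skips the stage).
#' @param bootstrap_B Neutrality-slope bootstrap replicates.
#' @param neutrality_unit `"gene"` or `"species"` regression unit.
#' @param seed Seed for all seeded stages.
#' @param outdir Output directory; `NULL` keeps the bundle in memory only.
#' @param zero_absent_cai Write 0 instead of NA for CAI of absent genes.
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL,
                            qc = qc_policy(),
                            codon_set_mode = "standard_60",
                            permutations = 10000L, bootstrap_B = 10000L,
                            neutrality_unit = "gene",
                            seed = 12345L, outdir = NULL,
                            zero_absent_cai = FALSE) {
  if (is.null(input_dir) && is.null(cohort)) {
    stop("either input_dir or cohort must be given", call. = FALSE)
  }
  if (!is.null(input_dir) && !file.exists(file.path(input_dir, "metadata.tsv"))) {
    stop("input_dir has no metadata.tsv", call. = FALSE)
  }
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  stopifnot(inherits(qc, "qc_policy"),
            codon_set_mode %in% c("standard_60", "code_aware"),
            permutations >= 0, bootstrap_B >= 100,
            neutrality_unit %in% c("gene", "species"))
  structure(
    list(input_dir = input_dir, cohort = cohort, qc = qc,
         codon_set_mode = codon_set_mode,
         permutations = as.integer(permutations),
         bootstrap_B = as.integer(bootstrap_B),
         neutrality_unit = neutrality_unit,
         seed = as.integer(seed), outdir = outdir,
         zero_absent_cai = isTRUE(zero_absent_cai)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments, with QC
#' thresholds nested under `qc:` (max_ambiguous_fraction,
#' min_nuclear_length, min_codons_for_enc).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc_args <- y$qc %||% list()
  y$qc <- do.call(qc_policy, qc_args)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_species_records <- function(config) {
  if (!is.null(config$cohort)) {
    return(generate_cohort(config$cohort)$species)
  }
  meta <- utils::read.delim(file.path(config$input_dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  base <- config$input_dir
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    list(
      species_id = m$species_id, order_label = m$order_label,
      mito_genes = if (nzchar(m$mito_path %||% "")) {
        read_genbank_cds(resolve(m$mito_path), species_id = m$species_id)
      } else list(),
      nuclear_genes = if (nzchar(m$nuclear_path %||% "")) {
        read_fasta_cds(resolve(m$nuclear_path),
                       default_species = m$species_id)
      } else list()
    )
  })
}

#' Run the full codon-usage analysis pipeline
#'
#' Executes all stages in order — QC, codon quantification, RSCU,
#' hierarchical clustering, PCA, PERMANOVA (+ dispersion check), skews,
#' ENC-GC3 deviation, neutrality regression with bootstrap, CAI
#' (self-referenced per species), Kruskal-Wallis order tests, mitonuclear
#' coadaptation — and returns (optionally writes) the output bundle. A
#' species failing QC entirely is dropped with a logged reason; the run
#' aborts only when no species survives.
#'
#' @param config A `pipeline_config`.
#' @return An `output_bundle` list of tables, fit objects and the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("mitocub %s | seed %d | codon set %s",
      as.character(utils::packageVersion("mitocub")), config$seed,
      config$codon_set_mode)

  species <- load_species_records(config)
  say("loaded %d species records", length(species))

  qc_logs <- list()
  kept <- list()
  for (sp in species) {
    qm <- qc_filter(sp$mito_genes, config$qc)
    qn <- qc_filter(sp$nuclear_genes, config$qc)
    qc_logs[[length(qc_logs) + 1L]] <- rbind(qm$log, qn$log)
    if (!length(qm$retained) && !length(qn$retained)) {
      say("species %s dropped: no CDS survived QC", sp$species_id)
      next
    }
    sp$mito_genes <- qm$retained
    sp$nuclear_genes <- qn$retained
    kept[[length(kept) + 1L]] <- sp
  }
  if (!length(kept)) stop("no species surviving QC", call. = FALSE)
  species <- kept
  qc_log <- do.call(rbind, qc_logs)
  say("QC: %d species retained, %d rejections/trims logged",
      length(species), nrow(qc_log))

  orders <- stats::setNames(
    vapply(species, `[[`, character(1), "order_label"),
    vapply(species, `[[`, character(1), "species_id"))

  # per-gene metrics with per-species self-referenced CAI weights (mito)
  gene_rows <- list()
  rscu_profiles <- list(mito = list(), nuclear = list())
  skew_rows <- list()
  for (sp in species) {
    for (comp in c("mito", "nuclear")) {
      genes <- sp[[if (comp == "mito") "mito_genes" else "nuclear_genes"]]
      if (!length(genes)) next
      weights <- NULL
      if (comp == "mito") {
        pooled <- sum_codon_counts(lapply(genes, count_codons))
        weights <- reference_weights(
          pooled, sprintf("pooled %d mito PCGs of %s", length(genes),
                          sp$species_id))
      }
      for (g in genes) {
        gm <- gene_metrics(g, weights = weights)
        gm$order_label <- sp$order_label
        gene_rows[[length(gene_rows) + 1L]] <- gm
      }
      concat <- concatenate_cds(genes)
      rscu_profiles[[comp]][[sp$species_id]] <-
        local({
          pr <- compute_rscu(count_codons(concat))
          pr$unit_id <- sp$species_id
          pr
        })
      sk <- compute_skews(concat)
      skew_rows[[length(skew_rows) + 1L]] <- data.frame(
        species_id = sp$species_id, order_label = sp$order_label,
        compartment = comp, at_skew = sk[["at_skew"]],
        gc_skew = sk[["gc_skew"]], n_codons = nchar(concat$sequence) / 3,
        stringsAsFactors = FALSE)
    }
  }
  gene_metrics_tab <- do.call(rbind, gene_rows)
  skew_tab <- do.call(rbind, skew_rows)
  say("computed metrics for %d gene units", nrow(gene_metrics_tab))

  # multivariate structure per compartment
  multivar <- list()
  for (comp in c("mito", "nuclear")) {
    profs <- rscu_profiles[[comp]]
    if (length(profs) < 3L) next
    mode <- if (config$codon_set_mode == "standard_60") {
      "standard_60"
    } else "code_aware"
    mat <- assemble_matrix(unname(profs), codon_set_mode = mode)
    smat <- zscore_columns(mat)
    ord <- pca_rscu(smat)
    labs <- orders[rownames(smat$values)]
    res <- list(matrix = mat, scaled = smat, pca = ord,
                leaf_order = hierarchical_order(smat))
    if (config$permutations > 0L && length(unique(labs)) >= 2L &&
        all(table(labs) >= 2L)) {
      res$permanova <- permanova(smat, labs,
                                 permutations = config$permutations,
                                 seed = config$seed)
      res$dispersion <- dispersion_test(smat, labs,
                                        permutations = min(999L,
                                                           config$permutations),
                                        seed = config$seed)
      say("%s PERMANOVA: F %.3f, R2 %.3f, p %.4g", comp,
          res$permanova$pseudo_f, res$permanova$r_squared,
          res$permanova$p_value)
    } else if (config$permutations == 0L) {
      say("%s PERMANOVA stage skipped (permutations = 0)", comp)
    }
    multivar[[comp]] <- res
  }

  # selection diagnostics per compartment
  selection <- list()
  for (comp in c("mito", "nuclear")) {
    pts <- gene_metrics_tab[gene_metrics_tab$compartment == comp &
                              !is.na(gene_metrics_tab$enc) &
                              !is.na(gene_metrics_tab$gc3s) &
                              gene_metrics_tab$n_codons >=
                                config$qc$min_codons_for_enc, ]
    if (nrow(pts) < 3L) next
    dev <- enc_deviation(pts)
    fit <- tryCatch(
      bootstrap_slope(pts[, c("species_id", "gc12", "gc3", "n_codons")],
                      B = config$bootstrap_B, seed = config$seed,
                      unit = config$neutrality_unit),
      error = function(e) NULL)
    kw <- tryCatch(
      order_level_test(pts, metrics = intersect(c("enc", "gc3s", "cai"),
                                                names(pts)[colSums(!is.na(pts)) > 0])),
      error = function(e) NULL)
    if (!is.null(fit)) {
      say("%s neutrality slope %.3f [%.3f, %.3f]", comp, fit$slope,
          fit$slope_ci[1], fit$slope_ci[2])
    }
    selection[[comp]] <- list(enc_deviation = dev, neutrality = fit,
                              order_tests = kw)
  }

  # mitonuclear coadaptation
  coadapt <- NULL
  shared <- intersect(names(rscu_profiles$mito), names(rscu_profiles$nuclear))
  if (length(shared)) {
    coadapt <- coadaptation_table(rscu_profiles$mito[shared],
                                  rscu_profiles$nuclear[shared])
    coadapt$order_label <- unname(orders[coadapt$species_id])
    say("coadaptation: %s",
        paste(names(table(coadapt$class_label)),
              table(coadapt$class_label), sep = "=", collapse = ", "))
  }

  bundle <- structure(
    list(config = config, qc_log = qc_log,
         gene_metrics = gene_metrics_tab, skews = skew_tab,
         rscu_profiles = rscu_profiles, multivariate = multivar,
         selection = selection, coadaptation = coadapt, log = log),
    class = "output_bundle"
  )
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

rscu_long_table <- function(profiles_by_comp) {
  rows <- list()
  for (comp in names(profiles_by_comp)) {
    for (p in profiles_by_comp[[comp]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = p$unit_id, compartment = comp,
        codon = names(p$rscu),
        amino_acid = p$code$codon_to_aa[names(p$rscu)],
        rscu = unname(p$rscu), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an output bundle to disk
#'
#' Writes the tidy CSV tables, fit/test JSONs, the config snapshot and the
#' run log. Reruns with identical config and inputs are byte-identical (no
#' timestamps enter any output).
#'
#' @param bundle An `output_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  wcsv(bundle$gene_metrics, "gene_metrics.csv")
  wcsv(bundle$skews, "skews.csv")
  wcsv(rscu_long_table(bundle$rscu_profiles), "rscu_long.csv")
  wcsv(bundle$qc_log, "qc_log.csv")
  for (comp in names(bundle$multivariate)) {
    mv <- bundle$multivariate[[comp]]
    wcsv(data.frame(unit_id = rownames(mv$matrix$values),
                    mv$matrix$values, check.names = FALSE),
         sprintf("rscu_matrix_%s.csv", comp))
    wcsv(data.frame(unit_id = rownames(mv$pca$scores),
                    mv$pca$scores[, seq_len(min(5, ncol(mv$pca$scores)))],
                    check.names = FALSE),
         sprintf("pca_scores_%s.csv", comp))
    wcsv(data.frame(codon = rownames(mv$pca$loadings),
                    mv$pca$loadings[, seq_len(min(5, ncol(mv$pca$loadings)))],
                    check.names = FALSE),
         sprintf("pca_loadings_%s.csv", comp))
    if (!is.null(mv$permanova)) {
      jsonlite::write_json(
        c(mv$permanova[c("pseudo_f", "r_squared", "p_value",
                         "permutations")],
          list(dispersion_p = bundle$multivariate[[comp]]$dispersion$p_value)),
        file.path(dir, sprintf("permanova_%s.json", comp)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  for (comp in names(bundle$selection)) {
    sel <- bundle$selection[[comp]]
    wcsv(sel$enc_deviation$points[, c("species_id", "order_label", "gene",
                                      "enc", "gc3s", "d")],
         sprintf("enc_gc3_points_%s.csv", comp))
    if (!is.null(sel$neutrality)) {
      f <- sel$neutrality
      jsonlite::write_json(
        list(slope = f$slope, intercept = f$intercept,
             r_squared = f$r_squared, n_points = f$n_points,
             slope_ci_low = f$slope_ci[1], slope_ci_high = f$slope_ci[2],
             bootstrap_B = f$bootstrap_B, seed = f$seed),
        file.path(dir, sprintf("neutrality_%s.json", comp)),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(sel$order_tests)) {
      wcsv(sel$order_tests, sprintf("order_tests_%s.csv", comp))
    }
  }
  if (!is.null(bundle$coadaptation)) {
    wcsv(bundle$coadaptation, "coadaptation.csv")
  }
  cfg <- bundle$config
  cfg$outdir <- NULL  # where the run landed is not part of the analysis
  cfg$qc <- unclass(cfg$qc)
  cfg$cohort <- if (!is.null(cfg$cohort)) unclass(cfg$cohort) else NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Text report over an output bundle
#'
#' Per-order mean ENC (+/- SD) per compartment, the species-by-gene CAI
#' matrix over the 13 canonical mitochondrial genes (absent genes NA, or 0
#' under zero-absent-CAI), and coadaptation class counts.
#'
#' @param bundle An `output_bundle`.
#' @return Character vector of report lines (also printed with
#'   `cat`-friendly formatting by the caller); the CAI matrix is attached
#'   as attribute `cai_matrix`.
#' @export
write_report <- function(bundle) {
  gm <- bundle$gene_metrics
  lines <- c("== Codon-usage analysis report ==", "")
  for (comp in unique(gm$compartment)) {
    lines <- c(lines, sprintf("-- Mean ENC by order (%s) --", comp))
    sub <- gm[gm$compartment == comp & !is.na(gm$enc), ]
    for (o in sort(unique(sub$order_label))) {
      v <- sub$enc[sub$order_label == o]
      lines <- c(lines, sprintf("%-20s %8.3f +/- %.3f  (n=%d)", o,
                                mean(v), stats::sd(v), length(v)))
    }
    lines <- c(lines, "")
  }
  mito <- gm[gm$compartment == "mito", ]
  cai_mat <- NULL
  if (nrow(mito)) {
    sp_ids <- sort(unique(mito$species_id))
    cai_mat <- matrix(NA_real_, nrow = length(sp_ids),
                      ncol = length(MITO_PCG_ORDER),
                      dimnames = list(sp_ids, MITO_PCG_ORDER))
    hit <- mito$gene %in% MITO_PCG_ORDER
    cai_mat[cbind(mito$species_id[hit], mito$gene[hit])] <- mito$cai[hit]
    if (bundle$config$zero_absent_cai) cai_mat[is.na(cai_mat)] <- 0
    lines <- c(lines, "-- CAI matrix: 13 canonical mitochondrial genes --",
               paste(c("species", MITO_PCG_ORDER), collapse = "\t"))
    for (sp in sp_ids) {
      lines <- c(lines, paste(c(sp, ifelse(is.na(cai_mat[sp, ]), "NA",
                                           sprintf("%.3f", cai_mat[sp, ]))),
                              collapse = "\t"))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$coadaptation)) {
    tab <- table(bundle$coadaptation$class_label)
    lines <- c(lines, "-- Mitonuclear coadaptation classes --",
               sprintf("%-14s %d", names(tab), as.integer(tab)), "")
  }
  structure(lines, cai_matrix = cai_mat)
}
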