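# Mutation-selection cohort simulator.
#
# Codon probabilities follow a mutation-selection balance:
#   p(c) ∝ m(c) * w(c)^S
# where m(c) is the product over the codon's three positions of nucleotide
# propensities parameterized by a GC propensity and AT/GC skew parameters,
# w(c) is a codon-preference weight (unit mean within each synonymous
# family) and S >= 0 the selection strength. S = 0 reduces to the pure
# mutational distribution; large S concentrates mass on the max-preference
# codon. Defaults emulate the compositional contrast between AT-rich,
# strand-skewed invertebrate mitochondrial coding sequence and more
# balanced nuclear coding sequence.

#' Compartment model for the codon simulator
#'
#' @param gc_bias Target third-position (and, in free-composition mode,
#'   all-position) GC propensity in \[0, 1\].
#' @param at_skew_param,gc_skew_param Strand-asymmetry propensities in
#'   \[-1, 1\]: the A fraction among A+T is `(1 + at_skew_param) / 2`, the
#'   G fraction among G+C is `(1 + gc_skew_param) / 2`.
#' @param selection_strength S >= 0.
#' @param preference_weights Named numeric over the code's sense codons
#'   (unit mean within each family); `NULL` means no preference (all 1).
#' @param table_id NCBI translation table.
#' @return A `compartment_model` list.
#' @export
compartment_model <- function(gc_bias = 0.5, at_skew_param = 0,
                              gc_skew_param = 0, selection_strength = 0,
                              preference_weights = NULL, table_id = 1L) {
  stopifnot(gc_bias >= 0, gc_bias <= 1,
            abs(at_skew_param) <= 1, abs(gc_skew_param) <= 1,
            selection_strength >= 0)
  code <- load_genetic_code(table_id)
  if (is.null(preference_weights)) {
    preference_weights <- stats::setNames(
      rep(1, length(code$sense_codons)), code$sense_codons)
  } else {
    stopifnot(all(code$sense_codons %in% names(preference_weights)))
    preference_weights <- preference_weights[code$sense_codons]
    stopifnot(all(preference_weights > 0))
  }
  structure(
    list(gc_bias = gc_bias, at_skew_param = at_skew_param,
         gc_skew_param = gc_skew_param,
         selection_strength = selection_strength,
         preference_weights = preference_weights,
         table_id = as.integer(table_id), code = code),
    class = "compartment_model"
  )
}

#' Preset compartment models
#'
#' `"mito"`: AT-rich (GC propensity 0.25), T- over A-enriched
#' (at_skew -0.40) and G- over C-enriched (gc_skew +0.35) under the
#' invertebrate mitochondrial code (table 5) — the compositional regime of
#' helminth mitogenomes. `"nuclear"`: more balanced (GC propensity 0.45,
#' skews +0.05 / +0.04) under the standard code.
#'
#' @param compartment `"mito"` or `"nuclear"`.
#' @param ... Overrides passed to [compartment_model()].
#' @return A `compartment_model`.
#' @export
preset_model <- function(compartment = c("mito", "nuclear"), ...) {
  compartment <- match.arg(compartment)
  args <- if (compartment == "mito") {
    list(gc_bias = 0.25, at_skew_param = -0.40, gc_skew_param = 0.35,
         table_id = 5L)
  } else {
    list(gc_bias = 0.45, at_skew_param = 0.05, gc_skew_param = 0.04,
         table_id = 1L)
  }
  override <- list(...)
  args[names(override)] <- override
  do.call(compartment_model, args)
}

base_propensities <- function(model) {
  gc <- model$gc_bias
  c(A = (1 - gc) * (1 + model$at_skew_param) / 2,
    C = gc * (1 - model$gc_skew_param) / 2,
    G = gc * (1 + model$gc_skew_param) / 2,
    T = (1 - gc) * (1 - model$at_skew_param) / 2)
}

mutational_codon_weight <- function(model, codons) {
  props <- base_propensities(model)
  vapply(strsplit(codons, ""), function(b) prod(props[b]), numeric(1))
}

#' Codon distribution within a synonymous family
#'
#' `p(c) ∝ m(c) * w(c)^S` over the family's codons, where m is the
#' positionwise mutational propensity product and w the preference weight.
#'
#' @param model A `compartment_model`.
#' @param amino_acid One-letter amino-acid code present under the model's
#'   genetic code.
#' @return Named probability vector over the family's codons.
#' @export
codon_distribution <- function(model, amino_acid) {
  stopifnot(inherits(model, "compartment_model"))
  fam <- model$code$families[[amino_acid]]
  if (is.null(fam)) stop("amino acid ", amino_acid, " not in code",
                         call. = FALSE)
  m <- mutational_codon_weight(model, fam)
  w <- model$preference_weights[fam]
  p <- m * w^model$selection_strength
  p / sum(p)
}

# Distribution over all sense codons (free-composition mode): amino-acid
# identity is emergent from the nucleotide process, as in a purely
# mutational coding sequence.
sense_codon_distribution <- function(model) {
  codons <- model$code$sense_codons
  m <- mutational_codon_weight(model, codons)
  p <- m * model$preference_weights[codons]^model$selection_strength
  p / sum(p)
}

# Hydrophobic-leaning amino-acid composition typical of membrane-bound
# OXPHOS subunits; used as the fixed composition shared across
# compartments so codon-level effects are not confounded by protein
# composition. Normalized at use.
DEFAULT_AA_COMPOSITION <- c(
  A = 0.055, C = 0.015, D = 0.025, E = 0.025, F = 0.090, G = 0.055,
  H = 0.020, I = 0.100, K = 0.040, L = 0.160, M = 0.050, N = 0.050,
  P = 0.040, Q = 0.020, R = 0.025, S = 0.090, T = 0.055, V = 0.070,
  W = 0.020, Y = 0.040
)

#' Generate one coding sequence under a compartment model
#'
#' In `"fixed"` composition mode the amino-acid sequence is drawn from a
#' fixed composition (every amino acid of the code guaranteed present for
#' lengths >= 100 codons) and each site's codon from the within-family
#' mutation-selection distribution. In `"free"` mode codons are drawn
#' directly from the whole-sense-codon distribution, so amino-acid
#' composition itself tracks the mutational process (the neutral regime in
#' which first/second-position GC follows the same propensity as GC3). No
#' internal stops arise by construction; a terminal stop codon valid under
#' the model's code is appended.
#'
#' @param model A `compartment_model`.
#' @param length_codons Gene length in codons (excluding the stop).
#' @param seed Optional RNG seed for a reproducible single gene.
#' @param composition `"fixed"` or `"free"`.
#' @param aa_probs Amino-acid composition for fixed mode.
#' @param species_id,gene,compartment Labels for the returned `cds`.
#' @return A `cds` passing default QC by construction.
#' @export
generate_gene <- function(model, length_codons, seed = NULL,
                          composition = c("fixed", "free"),
                          aa_probs = DEFAULT_AA_COMPOSITION,
                          species_id = "sim", gene = "simgene",
                          compartment = c("mito", "nuclear")) {
  composition <- match.arg(composition)
  compartment <- match.arg(compartment)
  stopifnot(length_codons >= 1L)
  if (!is.null(seed)) {
    old <- .Random.seed_safe_get()
    on.exit(.Random.seed_safe_restore(old), add = TRUE)
    set.seed(seed)
  }
  code <- model$code
  if (composition == "free") {
    p <- sense_codon_distribution(model)
    codons <- sample(names(p), length_codons, replace = TRUE, prob = p)
  } else {
    aas <- intersect(names(aa_probs), names(code$families))
    aa_seq <- sample(aas, length_codons, replace = TRUE,
                     prob = aa_probs[aas])
    if (length_codons >= 100L) {
      # guarantee presence of every amino acid
      slots <- sample.int(length_codons, length(aas))
      aa_seq[slots] <- sample(aas)
    }
    codons <- character(length_codons)
    for (aa in unique(aa_seq)) {
      ix <- which(aa_seq == aa)
      p <- codon_distribution(model, aa)
      codons[ix] <- sample(names(p), length(ix), replace = TRUE, prob = p)
    }
  }
  seq <- paste(c(codons, code$stop_codons[1]), collapse = "")
  new_cds(species_id = species_id, compartment = compartment, gene = gene,
          sequence = seq, table_id = model$table_id)
}

#' Cohort specification for the simulator
#'
#' @param n_species Total species (split as evenly as possible across
#'   orders).
#' @param orders Character vector of order labels.
#' @param mito_genes_per_species Number of mitochondrial genes (<= 13;
#'   canonical labels are used).
#' @param nuclear_genes_per_species Number of nuclear transcripts.
#' @param gene_length_codons Integer range (min, max) of gene lengths.
#' @param coupling `"shared"` (nuclear preferences identical to mito) or
#'   `"independent"`.
#' @param selection_strength S applied in both compartments.
#' @param sigma_species,sigma_order SDs of the per-codon log-preference
#'   species and order effects.
#' @param composition `"fixed"` or `"free"` (see [generate_gene()]).
#' @param mito_gc_range,nuclear_gc_range Optional (min, max) ranges from
#'   which per-species GC propensities are drawn uniformly; `NULL` keeps
#'   the preset value for every species.
#' @param seed Cohort RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_species = 30L,
                        orders = c("Alphida", "Betida", "Gammida"),
                        mito_genes_per_species = 13L,
                        nuclear_genes_per_species = 30L,
                        gene_length_codons = c(150L, 520L),
                        coupling = c("shared", "independent"),
                        selection_strength = 1.5,
                        sigma_species = 1.0,
                        sigma_order = 0.5,
                        composition = c("fixed", "free"),
                        mito_gc_range = NULL,
                        nuclear_gc_range = NULL,
                        seed = 12345L) {
  coupling <- match.arg(coupling)
  composition <- match.arg(composition)
  stopifnot(n_species >= 2L, mito_genes_per_species >= 1L,
            mito_genes_per_species <= 13L,
            length(gene_length_codons) == 2L)
  structure(
    list(n_species = as.integer(n_species), orders = orders,
         mito_genes_per_species = as.integer(mito_genes_per_species),
         nuclear_genes_per_species = as.integer(nuclear_genes_per_species),
         gene_length_codons = as.integer(gene_length_codons),
         coupling = coupling, selection_strength = selection_strength,
         sigma_species = sigma_species, sigma_order = sigma_order,
         composition = composition,
         mito_gc_range = mito_gc_range, nuclear_gc_range = nuclear_gc_range,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Draw a preference-weight vector: per-codon log-weights = order effect +
# species effect, exponentiated and normalized to unit mean within each
# synonymous family.
draw_preferences <- function(code, order_log_effect, sigma_species) {
  lw <- order_log_effect + stats::rnorm(length(code$sense_codons),
                                        0, sigma_species)
  w <- stats::setNames(exp(lw), code$sense_codons)
  for (fam in code$families) {
    w[fam] <- w[fam] / mean(w[fam])
  }
  w
}

#' Generate a synthetic mitonuclear cohort
#'
#' Builds species with a mitochondrial compartment from the AT-rich,
#' strand-skewed preset (table 5) and a nuclear compartment from the
#' balanced preset (table 1). Order-level perturbations of the preference
#' vectors give PCA/PERMANOVA recoverable group structure; `coupling`
#' controls whether the two compartments of a species share one preference
#' vector (coadaptation) or draw independent ones (decoupling). Fully
#' deterministic under the spec seed.
#'
#' @param spec A `cohort_spec`.
#' @return List with `species` (list of per-species records: `species_id`,
#'   `order_label`, `mito_genes`, `nuclear_genes`) and `truth` (the
#'   manifest: per-species models, preference vectors, coupling, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  set.seed(spec$seed)

  code_m <- load_genetic_code(5L)
  code_n <- load_genetic_code(1L)
  order_of <- rep(spec$orders, length.out = spec$n_species)
  order_of <- order_of[order(match(order_of, spec$orders))]

  # per-order log-preference effects, one per compartment draw
  ord_fx_m <- lapply(spec$orders, function(o) {
    stats::rnorm(length(code_m$sense_codons), 0, spec$sigma_order)
  })
  names(ord_fx_m) <- spec$orders
  ord_fx_n <- lapply(spec$orders, function(o) {
    stats::rnorm(length(code_n$sense_codons), 0, spec$sigma_order)
  })
  names(ord_fx_n) <- spec$orders

  species <- vector("list", spec$n_species)
  truth <- vector("list", spec$n_species)
  mito_gene_names <- MITO_PCG_ORDER[seq_len(spec$mito_genes_per_species)]

  for (i in seq_len(spec$n_species)) {
    sp_id <- sprintf("sp%03d", i)
    ord <- order_of[i]

    gc_m <- if (is.null(spec$mito_gc_range)) 0.25 else
      stats::runif(1, spec$mito_gc_range[1], spec$mito_gc_range[2])
    gc_n <- if (is.null(spec$nuclear_gc_range)) 0.45 else
      stats::runif(1, spec$nuclear_gc_range[1], spec$nuclear_gc_range[2])

    w_m <- draw_preferences(code_m, ord_fx_m[[ord]], spec$sigma_species)
    w_n <- if (spec$coupling == "shared") {
      # same preference landscape, restricted to the nuclear code's codons
      wn <- w_m[code_n$sense_codons]
      for (fam in code_n$families) wn[fam] <- wn[fam] / mean(wn[fam])
      wn
    } else {
      draw_preferences(code_n, ord_fx_n[[ord]], spec$sigma_species)
    }

    model_m <- preset_model("mito", gc_bias = gc_m,
                            selection_strength = spec$selection_strength,
                            preference_weights = w_m)
    model_n <- preset_model("nuclear", gc_bias = gc_n,
                            selection_strength = spec$selection_strength,
                            preference_weights = w_n)

    lens_m <- sample(spec$gene_length_codons[1]:spec$gene_length_codons[2],
                     spec$mito_genes_per_species, replace = TRUE)
    mito_genes <- lapply(seq_along(mito_gene_names), function(k) {
      generate_gene(model_m, lens_m[k], composition = spec$composition,
                    species_id = sp_id, gene = mito_gene_names[k],
                    compartment = "mito")
    })
    lens_n <- sample(spec$gene_length_codons[1]:spec$gene_length_codons[2],
                     spec$nuclear_genes_per_species, replace = TRUE)
    nuclear_genes <- lapply(seq_len(spec$nuclear_genes_per_species),
                            function(k) {
      generate_gene(model_n, lens_n[k], composition = spec$composition,
                    species_id = sp_id, gene = sprintf("tr%04d", k),
                    compartment = "nuclear")
    })

    species[[i]] <- list(species_id = sp_id, order_label = ord,
                         mito_genes = mito_genes,
                         nuclear_genes = nuclear_genes)
    truth[[i]] <- list(species_id = sp_id, order_label = ord,
                       gc_bias_mito = gc_m, gc_bias_nuclear = gc_n,
                       at_skew_mito = model_m$at_skew_param,
                       gc_skew_mito = model_m$gc_skew_param,
                       selection_strength = spec$selection_strength,
                       coupling = spec$coupling,
                       pref_mito = as.list(w_m), pref_nuclear = as.list(w_n))
  }
  list(species = species,
       truth = list(spec = unclass(spec), per_species = truth))
}

# ---- cohort writers -------------------------------------------------------

format_genbank_origin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, 60L)
  lines <- vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1))
  lines
}

#' Write a species' mitochondrial genes as a GenBank flat file
#'
#' Genes are laid out sequentially on a synthetic contig; every fifth gene
#' is stored on the minus strand (the feature carries `complement(..)` and
#' the contig the reverse complement), exercising coding-orientation
#' recovery on read-back.
#'
#' @param genes List of mito `cds` objects for one species.
#' @param path Output path.
#' @param species_id Organism name written to the record.
#' @return `path`, invisibly.
#' @export
write_genbank_cohort_record <- function(genes, path, species_id) {
  pieces <- character(length(genes))
  feats <- character(0)
  pos <- 0L
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    len <- nchar(g$sequence)
    start1 <- pos + 1L
    end1 <- pos + len
    minus <- (k %% 5L == 0L)
    pieces[k] <- if (minus) reverse_complement(g$sequence) else g$sequence
    loc <- if (minus) sprintf("complement(%d..%d)", start1, end1) else
      sprintf("%d..%d", start1, end1)
    feats <- c(feats,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", g$gene),
               sprintf("                     /transl_table=%d", g$table_id))
    pos <- end1
  }
  genome <- paste(pieces, collapse = "")
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular     01-JAN-2026",
            gsub("\\s", "_", species_id), nchar(genome)),
    sprintf("DEFINITION  %s mitochondrion, synthetic cohort record.",
            species_id),
    "SOURCE      synthetic",
    sprintf("  ORGANISM  %s", species_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    feats,
    "ORIGIN",
    format_genbank_origin(genome),
    "//"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Per species: a GenBank flat file of the mitochondrial genes and a FASTA
#' of the nuclear transcripts; plus a cohort metadata TSV (species id,
#' order, file paths) and the ground-truth manifest as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The metadata table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(cohort$species, function(sp) {
    gb <- file.path(dir, paste0(sp$species_id, "_mito.gb"))
    fa <- file.path(dir, paste0(sp$species_id, "_nuclear.fasta"))
    write_genbank_cohort_record(sp$mito_genes, gb, sp$species_id)
    seqs <- Biostrings::DNAStringSet(
      vapply(sp$nuclear_genes, `[[`, character(1), "sequence"))
    names(seqs) <- vapply(sp$nuclear_genes, function(g) {
      paste0(g$species_id, "|", g$gene)
    }, character(1))
    Biostrings::writeXStringSet(seqs, fa)
    data.frame(species_id = sp$species_id, order_label = sp$order_label,
               mito_path = gb, nuclear_path = fa, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(meta)
}
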