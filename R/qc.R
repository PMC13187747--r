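# Quality control of coding sequences prior to codon-usage analysis.

#' Quality-control policy for coding sequences
#'
#' Defaults mirror the curation rules used throughout the package: reject
#' CDSs with more than 1% ambiguous nucleotides, nuclear CDSs shorter than
#' 150 nt, sequences with internal stop codons under their own genetic code,
#' and frameshifted sequences (length not a multiple of 3 after trimming a
#' trailing incomplete stop codon). Mitochondrial annotations frequently end
#' in an incomplete stop (T or TA completed by polyadenylation); a 1-2 nt
#' overhang is trimmed and logged rather than rejected.
#'
#' @param max_ambiguous_fraction Maximum tolerated N fraction (default 0.01).
#' @param min_nuclear_length Minimum nuclear CDS length in nt (default 150).
#' @param min_codons_for_enc Minimum codon count for ENC points (default 100).
#' @param reject_internal_stops,reject_frameshift Logical switches.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(max_ambiguous_fraction = 0.01,
                      min_nuclear_length = 150L,
                      min_codons_for_enc = 100L,
                      reject_internal_stops = TRUE,
                      reject_frameshift = TRUE) {
  stopifnot(max_ambiguous_fraction > 0, min_nuclear_length > 0,
            min_codons_for_enc > 0)
  structure(list(
    max_ambiguous_fraction = max_ambiguous_fraction,
    min_nuclear_length = as.integer(min_nuclear_length),
    min_codons_for_enc = as.integer(min_codons_for_enc),
    reject_internal_stops = isTRUE(reject_internal_stops),
    reject_frameshift = isTRUE(reject_frameshift)
  ), class = "qc_policy")
}

#' Filter coding sequences by quality-control rules
#'
#' Applies the policy rules in a fixed order (ambiguity, length, trailing
#' stop-overhang trimming, frameshift, internal stops) and returns both the
#' retained sequences and a rejection log. Filtering is total: no input
#' raises an error. Idempotent: filtering an already-filtered set changes
#' nothing.
#'
#' @param cds_list List of `cds` objects.
#' @param policy A `qc_policy`.
#' @return List with `retained` (list of `cds`, trailing overhangs trimmed),
#'   and `log` (data.frame: species_id, gene, compartment, action, rule,
#'   detail) covering both rejections and trims.
#' @export
qc_filter <- function(cds_list, policy = qc_policy()) {
  log <- list()
  note <- function(x, action, rule, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(
      species_id = x$species_id, gene = x$gene, compartment = x$compartment,
      action = action, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }
  retained <- list()
  for (x in cds_list) {
    n <- nchar(x$sequence)
    n_amb <- n - nchar(gsub("N", "", x$sequence))
    if (n == 0L) {
      note(x, "rejected", "empty", "zero-length sequence")
      next
    }
    if (n_amb / n > policy$max_ambiguous_fraction) {
      note(x, "rejected", "ambiguous",
           sprintf("%.3f N fraction > %.3f", n_amb / n,
                   policy$max_ambiguous_fraction))
      next
    }
    if (x$compartment == "nuclear" && n < policy$min_nuclear_length) {
      note(x, "rejected", "min_length",
           sprintf("%d nt < %d nt", n, policy$min_nuclear_length))
      next
    }
    # trailing incomplete stop codon on mito genes: 1-2 nt overhang whose
    # bases are a prefix of a stop codon of the active code
    seq <- x$sequence
    overhang <- n %% 3L
    if (overhang > 0L && x$compartment == "mito") {
      tail_nt <- substr(seq, n - overhang + 1L, n)
      code <- load_genetic_code(x$table_id)
      if (any(startsWith(code$stop_codons, tail_nt))) {
        seq <- substr(seq, 1L, n - overhang)
        note(x, "trimmed", "trailing_stop_overhang",
             sprintf("trimmed %d nt ('%s')", overhang, tail_nt))
        x$sequence <- seq
        n <- nchar(seq)
        overhang <- 0L
      }
    }
    if (policy$reject_frameshift && n %% 3L != 0L) {
      note(x, "rejected", "frameshift",
           sprintf("length %d not a multiple of 3", n))
      next
    }
    if (policy$reject_internal_stops && n %% 3L == 0L && n >= 3L) {
      code <- load_genetic_code(x$table_id)
      codons <- split_codons(seq)
      body <- codons[-length(codons)]  # a terminal stop is legitimate
      internal <- body[body %in% code$stop_codons]
      if (length(internal)) {
        note(x, "rejected", "internal_stop",
             sprintf("%d internal stop codon(s), first '%s'",
                     length(internal), internal[1]))
        next
      }
    }
    retained[[length(retained) + 1L]] <- x
  }
  log_df <- if (length(log)) do.call(rbind, log) else data.frame(
    species_id = character(0), gene = character(0), compartment = character(0),
    action = character(0), rule = character(0), detail = character(0),
    stringsAsFactors = FALSE)
  list(retained = retained, log = log_df)
}

#' Write a QC rejection/trim log as TSV
#'
#' @param log Data frame from [qc_filter()].
#' @param path Output path.
#' @export
write_qc_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate coding sequences within one species and compartment
#'
#' Joins QC-passed CDSs into the single per-species, per-compartment unit
#' used for species-level summaries (skews, neutrality, ENC-GC3). The codon
#' sequence of the result is the exact in-order concatenation of the parts,
#' so codon counts of the whole equal the sum of per-gene counts (terminal
#' stop codons stay in place; they are tallied separately and excluded from
#' all downstream metrics by [count_codons()]). Gene order is deterministic:
#' canonical 13-gene order for mitochondrial input (unmatched names last,
#' lexicographic), lexicographic for nuclear.
#'
#' @param records List of `cds` sharing species and compartment, lengths
#'   multiples of 3.
#' @param species_id,compartment Consistency checks; default from records.
#' @return A single `cds` named `"concatenated"`.
#' @export
concatenate_cds <- function(records, species_id = NULL, compartment = NULL) {
  if (!length(records)) stop("no records to concatenate", call. = FALSE)
  sp <- unique(vapply(records, `[[`, character(1), "species_id"))
  cp <- unique(vapply(records, `[[`, character(1), "compartment"))
  if (length(sp) != 1L || length(cp) != 1L) {
    stop("records mix species or compartments: ",
         paste(sp, collapse = ","), " / ", paste(cp, collapse = ","),
         call. = FALSE)
  }
  if (!is.null(species_id) && species_id != sp) {
    stop("species_id mismatch", call. = FALSE)
  }
  if (!is.null(compartment) && compartment != cp) {
    stop("compartment mismatch", call. = FALSE)
  }
  genes <- vapply(records, `[[`, character(1), "gene")
  if (cp == "mito") {
    rank <- match(genes, MITO_PCG_ORDER)
    ord <- order(is.na(rank), rank, genes)
  } else {
    ord <- order(genes)
  }
  tables <- vapply(records, `[[`, integer(1), "table_id")
  lens <- vapply(records, function(x) nchar(x$sequence), integer(1))
  if (any(lens %% 3L != 0L)) {
    stop("all inputs must have length a multiple of 3", call. = FALSE)
  }
  seq <- paste(vapply(records[ord], `[[`, character(1), "sequence"),
               collapse = "")
  new_cds(species_id = sp, compartment = cp, gene = "concatenated",
          sequence = seq, table_id = tables[ord][1])
}
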