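# Sequence containers and file readers.
#
# A coding sequence is represented as a plain list of class "cds":
#   species_id, compartment ("mito"/"nuclear"), gene, sequence (A/C/G/T/N,
#   coding orientation), table_id (NCBI translation table).
# Internal coordinates are 0-based half-open; GenBank's 1-based inclusive
# spans are converted once, at the parser boundary.

#' Construct a coding-sequence record
#'
#' @param species_id Species identifier.
#' @param compartment `"mito"` or `"nuclear"`.
#' @param gene Gene label (one of the 13 canonical mitochondrial genes, or a
#'   transcript id for nuclear CDSs).
#' @param sequence Nucleotide string over `A,C,G,T,N`, coding orientation.
#' @param table_id NCBI translation-table number for the sequence.
#' @return An object of class `cds`.
#' @export
new_cds <- function(species_id, compartment = c("mito", "nuclear"),
                    gene, sequence, table_id = if (compartment[1] == "mito") 5L else 1L) {
  compartment <- match.arg(compartment)
  sequence <- toupper(gsub("U", "T", toupper(sequence)))
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N,U}", call. = FALSE)
  }
  structure(
    list(species_id = as.character(species_id), compartment = compartment,
         gene = as.character(gene), sequence = sequence,
         table_id = as.integer(table_id)),
    class = "cds"
  )
}

#' @export
print.cds <- function(x, ...) {
  cat(sprintf("<cds> %s | %s | %s | %d nt | table %d\n",
              x$species_id, x$compartment, x$gene, nchar(x$sequence),
              x$table_id))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}

#' Split a coding sequence into frame-0 codons
#'
#' @param seq Nucleotide string; length must be a multiple of 3.
#' @return Character vector of triplets.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Gene-name normalization: map the synonym zoo in GenBank annotations onto
# the 13 canonical labels. Unmatched names are returned untouched.
GENE_SYNONYMS <- local({
  syn <- list(
    ATP6 = c("ATP6", "ATPASE6", "ATPASE 6", "ATP SYNTHASE F0 SUBUNIT 6", "A6"),
    ATP8 = c("ATP8", "ATPASE8", "ATPASE 8", "ATP SYNTHASE F0 SUBUNIT 8", "A8"),
    COX1 = c("COX1", "COXI", "COI", "CO1", "COX-1",
             "CYTOCHROME C OXIDASE SUBUNIT 1", "CYTOCHROME C OXIDASE SUBUNIT I"),
    COX2 = c("COX2", "COXII", "COII", "CO2", "COX-2",
             "CYTOCHROME C OXIDASE SUBUNIT 2", "CYTOCHROME C OXIDASE SUBUNIT II"),
    COX3 = c("COX3", "COXIII", "COIII", "CO3", "COX-3",
             "CYTOCHROME C OXIDASE SUBUNIT 3", "CYTOCHROME C OXIDASE SUBUNIT III"),
    COB  = c("COB", "CYTB", "CYT B", "CYTOCHROME B", "CB"),
    NAD1 = c("NAD1", "ND1", "NADH1", "NADH DEHYDROGENASE SUBUNIT 1"),
    NAD2 = c("NAD2", "ND2", "NADH2", "NADH DEHYDROGENASE SUBUNIT 2"),
    NAD3 = c("NAD3", "ND3", "NADH3", "NADH DEHYDROGENASE SUBUNIT 3"),
    NAD4 = c("NAD4", "ND4", "NADH4", "NADH DEHYDROGENASE SUBUNIT 4"),
    NAD4L = c("NAD4L", "ND4L", "NADH4L", "NADH DEHYDROGENASE SUBUNIT 4L"),
    NAD5 = c("NAD5", "ND5", "NADH5", "NADH DEHYDROGENASE SUBUNIT 5"),
    NAD6 = c("NAD6", "ND6", "NADH6", "NADH DEHYDROGENASE SUBUNIT 6")
  )
  flat <- stats::setNames(rep(names(syn), lengths(syn)), unlist(syn))
  flat
})

#' Normalize a mitochondrial gene name to its canonical label
#'
#' @param name Raw gene or product qualifier.
#' @return Canonical label (e.g. `"COX1"`, `"NAD4L"`) when recognized,
#'   otherwise the uppercased input.
#' @export
normalize_gene_name <- function(name) {
  key <- toupper(trimws(name))
  out <- unname(GENE_SYNONYMS[key])
  ifelse(is.na(out), key, out)
}

# ---- GenBank flat-file parsing -------------------------------------------

parse_genbank_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- 1L
  # peel complement()/join()/order() wrappers (complement may wrap join)
  repeat {
    if (grepl("^complement\\(.*\\)$", loc)) {
      strand <- -strand
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    } else if (grepl("^(join|order)\\(.*\\)$", loc)) {
      loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    } else break
  }
  parts <- strsplit(loc, ",")[[1]]
  spans <- lapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums) || nums[2] < nums[1]) {
      stop("cannot parse GenBank location: ", p, call. = FALSE)
    }
    # convert 1-based inclusive -> 0-based half-open
    c(start0 = nums[1] - 1L, end0 = nums[2])
  })
  list(strand = strand, spans = spans)
}

#' Read CDS features from a GenBank flat file
#'
#' Parses a GenBank flat-file record (LOCUS/FEATURES/ORIGIN), extracts every
#' CDS feature, reverse-complements minus-strand features into coding
#' orientation, normalizes gene names onto the 13 canonical mitochondrial
#' labels via the gene/product qualifiers, and honors the
#' `/transl_table` qualifier (defaulting to the invertebrate mitochondrial
#' table 5 for mitochondrial records).
#'
#' @param path Path to a `.gb`/`.gbk` file, or a character vector of the
#'   record's lines via `text`.
#' @param text Optional character vector of record lines (overrides `path`).
#' @param compartment Compartment tag for the extracted CDSs.
#' @param species_id Species id; defaults to the ORGANISM/LOCUS name.
#' @param default_table Translation table assumed when `/transl_table` is
#'   absent.
#' @return List of `cds` objects, in feature-table order.
#' @export
read_genbank_cds <- function(path = NULL, text = NULL, compartment = "mito",
                             species_id = NULL, default_table = 5L) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines)) || !any(grepl("^ORIGIN", lines))) {
    stop("not a parseable GenBank flat file (missing LOCUS or ORIGIN)",
         call. = FALSE)
  }

  if (is.null(species_id)) {
    org <- grep("^\\s{0,4}ORGANISM", lines, value = TRUE)
    species_id <- if (length(org)) {
      trimws(sub("^\\s*ORGANISM\\s+", "", org[1]))
    } else {
      strsplit(trimws(sub("^LOCUS\\s+", "", lines[grepl("^LOCUS", lines)][1])),
               "\\s+")[[1]][1]
    }
  }

  origin_at <- grep("^ORIGIN", lines)[1]
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- gsub("U", "T", genome)
  genome <- gsub("[^ACGTN]", "N", genome)  # IUPAC ambiguity -> N

  feat_at <- grep("^FEATURES", lines)
  if (!length(feat_at)) return(list())
  feat_lines <- lines[(feat_at[1] + 1L):(origin_at - 1L)]

  # group feature blocks: a new feature starts at indent 5 with a key
  starts <- grep("^ {1,10}\\S", feat_lines)
  starts <- starts[!grepl("^ {12,}", feat_lines[starts])]
  if (!length(starts)) return(list())
  blocks <- split(feat_lines,
                  findInterval(seq_along(feat_lines), starts))

  out <- list()
  for (blk in blocks) {
    key <- strsplit(trimws(blk[1]), "\\s+")[[1]][1]
    if (!identical(key, "CDS")) next
    # location may continue over lines until the first qualifier
    qual_start <- grep("^\\s+/", blk)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(blk)
    loc <- paste(gsub("\\s", "", sub("^\\s*CDS", "", blk[1:loc_end])),
                 collapse = "")
    quals <- paste(trimws(blk[-seq_len(loc_end)]), collapse = " ")
    get_qual <- function(name) {
      m <- regmatches(quals,
                      regexpr(sprintf('/%s=("[^"]*"|[^ /]+)', name), quals))
      if (!length(m)) return(NA_character_)
      gsub('^"|"$', "", sub(sprintf("^/%s=", name), "", m))
    }

    parsed <- parse_genbank_location(loc)
    for (sp in parsed$spans) {
      if (sp["end0"] > nchar(genome)) {
        stop("CDS coordinates exceed sequence length (",
             sp["end0"], " > ", nchar(genome), ")", call. = FALSE)
      }
    }
    pieces <- vapply(parsed$spans, function(sp) {
      substr(genome, sp["start0"] + 1L, sp["end0"])
    }, character(1))
    seq <- paste(pieces, collapse = "")
    if (parsed$strand < 0L) seq <- reverse_complement(seq)

    gene <- get_qual("gene")
    if (is.na(gene)) gene <- get_qual("product")
    if (is.na(gene)) gene <- "unknown"
    tt <- suppressWarnings(as.integer(get_qual("transl_table")))
    if (is.na(tt)) tt <- as.integer(default_table)

    out[[length(out) + 1L]] <- new_cds(
      species_id = species_id, compartment = compartment,
      gene = normalize_gene_name(gene), sequence = seq, table_id = tt)
  }
  out
}

#' Read CDS entries from a FASTA file
#'
#' One `cds` per FASTA entry, in file order. Lowercase input is uppercased
#' and `U` normalized to `T`. The species and gene are taken from the
#' header via `header_pattern`, a regex with named-by-position capture
#' groups `(species)(gene)`; when the pattern does not match, the gene
#' falls back to the full first header token and the species to
#' `default_species`.
#'
#' @param path FASTA path.
#' @param compartment Compartment tag.
#' @param default_table Translation table for the entries.
#' @param header_pattern Regex with two capture groups (species, gene);
#'   `NULL` disables header parsing.
#' @param default_species Species id used when the header yields none.
#' @return List of `cds` objects.
#' @export
read_fasta_cds <- function(path, compartment = "nuclear", default_table = 1L,
                           header_pattern = "^(\\S+)\\|(\\S+)$",
                           default_species = NA_character_) {
  # read as raw strings so RNA (U) and lowercase input survive to the
  # normalization step below
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  headers <- names(set)
  first_tok <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  ids <- first_tok
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids; suffixing duplicates", call. = FALSE)
    ids <- make.unique(ids, sep = "_dup")
  }
  seqs <- gsub("U", "T", toupper(unname(as.character(set))))
  lapply(seq_along(set), function(i) {
    species <- default_species
    gene <- ids[i]
    if (!is.null(header_pattern) && grepl(header_pattern, first_tok[i])) {
      m <- regmatches(first_tok[i], regexec(header_pattern, first_tok[i]))[[1]]
      if (length(m) >= 3L) {
        species <- m[2]
        gene <- m[3]
      }
    }
    if (is.na(species)) {
      species <- tools::file_path_sans_ext(basename(path))
    }
    new_cds(species_id = species, compartment = compartment, gene = gene,
            sequence = gsub("[^ACGTN]", "N", seqs[i]),
            table_id = default_table)
  })
}
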