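# NCBI translation tables supported out of the box. Others present in
# Biostrings' registry can be added here after checking their family
# structure is meaningful for codon-usage work.
SUPPORTED_CODE_TABLES <- c(1L, 2L, 5L, 9L, 13L, 14L)

ALL_CODONS <- as.vector(outer(
  outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
  c("T", "C", "A", "G"), paste0
))

# Canonical mitochondrial protein-coding gene labels, in conventional order.
MITO_PCG_ORDER <- c(
  "ATP6", "ATP8", "COX1", "COX2", "COX3", "COB",
  "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6"
)

#' Load an NCBI genetic code
#'
#' Returns the full 64-codon mapping for an NCBI translation table together
#' with the synonymous-family structure needed by the codon-usage metrics:
#' family membership, family (degeneracy) sizes, sense/stop partition, start
#' codons, and the maximal effective number of codons for the table (its
#' sense-codon count; 61 for the standard code, 62 for the invertebrate
#' mitochondrial code where TGA encodes Trp).
#'
#' @param table_id Integer NCBI translation-table number. Supported:
#'   1 (standard), 2 (vertebrate mito), 5 (invertebrate mito),
#'   9 (echinoderm/flatworm mito), 13 (ascidian mito), 14 (alternative
#'   flatworm mito).
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `name`, `codon_to_aa` (named character over all 64 codons,
#'   stops as `"*"`), `start_codons`, `stop_codons`, `sense_codons`,
#'   `families` (list amino acid -> codon vector), `family_size` (named
#'   integer per codon), and `enc_max`.
#' @examples
#' code5 <- load_genetic_code(5)
#' code5$codon_to_aa[["TGA"]]  # "W" under the invertebrate mito code
#' code5$enc_max               # 62
#' @export
load_genetic_code <- function(table_id) {
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || is.na(table_id) ||
      !table_id %in% SUPPORTED_CODE_TABLES) {
    stop("unsupported genetic-code table id: ", table_id,
         " (supported: ", paste(SUPPORTED_CODE_TABLES, collapse = ", "), ")",
         call. = FALSE)
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  codon_to_aa <- stats::setNames(as.character(map), names(map))[ALL_CODONS]
  stopifnot(length(codon_to_aa) == 64L, !anyNA(codon_to_aa))

  row <- Biostrings::GENETIC_CODE_TABLE[
    Biostrings::GENETIC_CODE_TABLE$id == as.character(table_id), ]
  starts_mask <- strsplit(row$Starts, "")[[1]]
  start_codons <- ALL_CODONS[starts_mask == "M"]

  stop_codons <- names(codon_to_aa)[codon_to_aa == "*"]
  sense_codons <- setdiff(names(codon_to_aa), stop_codons)
  families <- split(sense_codons, codon_to_aa[sense_codons])
  family_size <- stats::setNames(
    lengths(families)[codon_to_aa[sense_codons]], sense_codons)

  structure(
    list(
      table_id = table_id,
      name = row$name,
      codon_to_aa = codon_to_aa,
      start_codons = start_codons,
      stop_codons = stop_codons,
      sense_codons = sense_codons,
      families = families,
      family_size = family_size,
      enc_max = length(sense_codons)
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("NCBI genetic code table", x$table_id, "-", x$name, "\n")
  cat(" ", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stops (",
      paste(x$stop_codons, collapse = ", "), ")\n")
  cat("  degeneracy classes:",
      paste(sort(unique(lengths(x$families))), collapse = "/"), "\n")
  invisible(x)
}

#' Degenerate sense codons of a genetic code
#'
#' Codons belonging to synonymous families with at least two members,
#' i.e. the codons for which a synonymous choice exists.
#'
#' @param code A `genetic_code`.
#' @return Character vector of codons.
#' @export
degenerate_codons <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  names(code$family_size)[code$family_size >= 2L]
}

#' Shared codon sets used for cross-compartment comparison
#'
#' `codon_set("standard60")` is the 60-codon set used for species-by-codon
#' RSCU matrices: standard-code sense codons minus ATG and the three
#' stops. `codon_set("shared59")` further removes TGG, leaving the 59
#' degenerate standard-code sense codons used when correlating
#' mitochondrial against nuclear RSCU vectors. `codon_set("code_aware",
#' code)` returns the degenerate sense codons of an arbitrary code.
#'
#' @param mode One of `"standard60"`, `"shared59"`, `"code_aware"`.
#' @param code A `genetic_code`; required for `"code_aware"`.
#' @return Character vector of codons in fixed (amino-acid-grouped) order.
#' @export
codon_set <- function(mode = c("standard60", "shared59", "code_aware"),
                      code = NULL) {
  mode <- match.arg(mode)
  std <- load_genetic_code(1)
  ordered_by_aa <- function(codons, cd) {
    codons[order(cd$codon_to_aa[codons], codons)]
  }
  switch(mode,
    standard60 = ordered_by_aa(setdiff(std$sense_codons, "ATG"), std),
    shared59 = ordered_by_aa(setdiff(std$sense_codons, c("ATG", "TGG")), std),
    code_aware = {
      if (is.null(code)) stop("code_aware mode needs a genetic code")
      ordered_by_aa(degenerate_codons(code), code)
    }
  )
}
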