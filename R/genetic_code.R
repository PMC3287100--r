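# Standard genetic code lookup tables shared by every module.
#
# All tables are derived once, at package build, from Biostrings::GENETIC_CODE
# so the codon -> amino acid map has a single authoritative source. Codons are
# spelled in the DNA alphabet and ordered alphabetically everywhere; reports
# that want RNA spelling can substitute U for T at print time.

#' @importFrom Biostrings GENETIC_CODE
NULL

.codon_tables <- local({
  gc_map <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc_map))
  aa <- gc_map[codons]

  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  # Met and Trp have a single codon each: no synonymous choice to measure.
  syn_sense <- setdiff(sense, c("ATG", "TGG"))

  fams <- split(syn_sense, aa[syn_sense])
  degeneracy <- vapply(fams, length, integer(1))

  list(
    codons = codons,
    codon_aa = aa,
    stop_codons = stops,
    sense_codons = sense,
    syn_sense_codons = syn_sense,
    families = fams,
    degeneracy = degeneracy
  )
})

CODONS <- .codon_tables$codons
CODON_AA <- .codon_tables$codon_aa
STOP_CODONS <- .codon_tables$stop_codons
SENSE_CODONS <- .codon_tables$sense_codons
SYN_SENSE_CODONS <- .codon_tables$syn_sense_codons
SYN_FAMILIES <- .codon_tables$families
FAMILY_DEGENERACY <- .codon_tables$degeneracy

# Amino acids eligible for synthetic cohorts: the 18 multi-codon families
# plus Met and Trp.
COHORT_AMINO_ACIDS <- c(names(SYN_FAMILIES), "M", "W")

# Codons (sense, incl. ATG/TGG) available to each amino acid.
AA_CODONS <- split(SENSE_CODONS, CODON_AA[SENSE_CODONS])

#' Synonymous sense codons in canonical order
#'
#' Returns the 59 sense codons that carry synonymous-usage information:
#' the 61 non-stop codons minus ATG (Met) and TGG (Trp), alphabetically
#' ordered in DNA spelling. This is the fixed column order of every RSCU
#' vector and matrix produced by the package.
#'
#' @return Character vector of length 59.
#' @export
#' @examples
#' length(synonymous_codons())
synonymous_codons <- function() SYN_SENSE_CODONS

#' Amino acid encoded by each codon
#'
#' @param codons Character vector of DNA codons.
#' @return Character vector of one-letter amino acid codes (`"*"` for stops).
#' @export
#' @examples
#' codon_amino_acid(c("ATG", "TCT", "TAA"))
codon_amino_acid <- function(codons) {
  out <- CODON_AA[toupper(codons)]
  names(out) <- codons
  out
}
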