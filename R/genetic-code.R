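#' Standard genetic code tables
#'
#' Returns the standard (nuclear) genetic code as a pair of lookup tables:
#' `codon_to_aa`, a named character vector over the 64 codons, and
#' `aa_to_codons`, a list mapping each of the 20 amino acids to its set of
#' sense codons. Stop codons are kept separately in `stop_codons`.
#'
#' @return A list with elements `codon_to_aa`, `aa_to_codons`, `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$aa_to_codons[["W"]] # TGG only
#' @export
genetic_code <- function() {
  if (is.null(.hyb_cache$code)) {
    codons <- Biostrings::GENETIC_CODE
    by_aa <- split(names(codons), unname(codons))
    .hyb_cache$code <- list(
      codon_to_aa = codons,
      aa_to_codons = by_aa[setdiff(names(by_aa), "*")],
      stop_codons = by_aa[["*"]]
    )
  }
  .hyb_cache$code
}

.hyb_cache <- new.env(parent = emptyenv())

#' Codon degeneracy of amino acids
#'
#' Number of synonymous sense codons for each amino acid (1, 2, 3, 4 or 6 in
#' the standard code).
#'
#' @param aa Character vector of single-letter amino-acid codes.
#' @param code Genetic code tables, see [genetic_code()].
#' @return Integer vector, same length as `aa`.
#' @export
codon_degeneracy <- function(aa, code = genetic_code()) {
  deg <- lengths(code$aa_to_codons)
  bad <- !aa %in% names(deg)
  if (any(bad)) {
    stop("unknown amino-acid letter(s): ", paste(unique(aa[bad]), collapse = ", "),
         " (only the 20 standard one-letter codes are accepted)")
  }
  unname(deg[aa])
}

## Cached codon -> amino-acid lookup over the 64 unambiguous codons.
codon_aa_lookup <- function() {
  if (is.null(.hyb_cache$codon_aa)) {
    .hyb_cache$codon_aa <- Biostrings::GENETIC_CODE
  }
  .hyb_cache$codon_aa
}

## Translate one frame of a DNA character string by direct codon lookup;
## partial trailing codons are dropped and any codon containing a
## non-A/C/G/T base (e.g. N) translates to X, so it can never match a
## standard residue. Much faster than the S4 path for repeated scans.
frame_protein_chr <- function(dna, frame = 0L) {
  n_cod <- (nchar(dna) - frame) %/% 3L
  if (n_cod < 1L) return("")
  at <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
  aa <- unname(codon_aa_lookup()[substring(dna, at, at + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

translate_chr <- function(dna) frame_protein_chr(toupper(dna), 0L)

revcomp_chr <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
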