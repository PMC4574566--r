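## Built-in histone H3 reference sequences (mature numbering, 135 aa).
## H3.2 differs from H3.1 by C96S; H3.3 differs from H3.2 by A31S, S87A,
## V89I, M90G. The mature sequences are constructed from H3.1 by applying
## those substitutions so the diagnostic positions are correct by
## construction.

.h3_1_mature <- paste0(
  "ARTKQTARKSTGGKAPRKQLATKAARKSAP", # 1-30
  "ATGGVKKPHRYRPGTVALREIRRYQKSTEL", # 31-60
  "LIRKLPFQRLVREIAQDFKTDLRFQSSAVM", # 61-90
  "ALQEACEAYLVGLFEDTNLCAIHAKRVTIM", # 91-120
  "PKDIQLARRIRGERA"                 # 121-135
)

subst_at <- function(seq, pos, aa) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- aa[i]
  seq
}

#' Reference histone H3 proteins
#'
#' Mature (initiator-Met-cleaved, 135-aa) protein sequences of the canonical
#' mouse histone H3 variants H3.1, H3.2 and H3.3. These are the references
#' against which candidate proteins are grouped and annotated: H3.1/H3.2
#' carry the SAVM motif at mature positions 87-90, H3.3 carries AAIG.
#'
#' @return Named character vector (`H3.1`, `H3.2`, `H3.3`).
#' @export
h3_reference_proteins <- function() {
  h3_1 <- .h3_1_mature
  h3_2 <- subst_at(h3_1, 96, "S")
  h3_3 <- subst_at(h3_2, c(31, 87, 89, 90), c("S", "A", "I", "G"))
  c(H3.1 = h3_1, H3.2 = h3_2, H3.3 = h3_3)
}

#' The histone H3.2 screening query
#'
#' The 136-aa histone H3.2 protein (initiator Met plus the 135-aa mature
#' sequence) with mature numbering (`numbering_offset = 1`) and the
#' histone-fold core domain set to mature residues 63-135 — the default
#' query of the in silico hybridization screen.
#'
#' @param core_range Core-domain interval in mature numbering.
#' @return A [protein_query()] object.
#' @examples
#' nrow(make_windows(h3_query())) # 129 windows
#' @export
h3_query <- function(core_range = c(63L, 135L)) {
  protein_query(paste0("M", h3_reference_proteins()[["H3.2"]]),
                id = "H3.2", numbering_offset = 1L, core_range = core_range)
}

#' Deterministic reverse translation of a protein
#'
#' Picks one fixed codon per residue (the alphabetically first synonymous
#' codon), producing a canonical CDS whose translation is the input protein.
#' Used by the simulator to implant coding sequences; any realization works
#' because matching is performed over all synonymous codons.
#'
#' @param protein Amino-acid string.
#' @param code Genetic code tables.
#' @return DNA string of length `3 * nchar(protein)` (no stop codon).
#' @export
protein_to_cds <- function(protein, code = genetic_code()) {
  res <- strsplit(toupper(protein), "")[[1]]
  bad <- which(!res %in% names(code$aa_to_codons))
  if (length(bad)) {
    stop("unknown amino-acid letter '", res[bad[1]], "' at position ", bad[1])
  }
  paste(vapply(res, function(a) sort(code$aa_to_codons[[a]])[1], character(1)),
        collapse = "")
}
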