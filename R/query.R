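#' Build a protein query
#'
#' Wraps a query amino-acid sequence together with its numbering convention
#' and core-domain interval. Positions reported downstream (substitutions,
#' motifs, core range) use *mature* numbering: position 1 is the residue
#' after the cleaved initiator methionine when `numbering_offset = 1`, or the
#' first residue when `numbering_offset = 0`.
#'
#' @param sequence Amino-acid string (single-letter codes; upper-cased on
#'   input). Non-standard letters (B, J, O, U, X, Z) are rejected.
#' @param id Query identifier.
#' @param numbering_offset 0 or 1; number of leading residues (the initiator
#'   Met) excluded from mature numbering.
#' @param core_range Length-2 integer vector, inclusive residue interval of
#'   the core domain in mature numbering.
#' @return An object of class `hyb_query`.
#' @seealso [h3_query()] for the built-in histone H3.2 query.
#' @export
protein_query <- function(sequence, id = "query", numbering_offset = 0L,
                          core_range = NULL) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  letters_ok <- names(genetic_code()$aa_to_codons)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% letters_ok)
  if (length(bad)) {
    stop("non-standard amino-acid letter '", res[bad[1]],
         "' at position ", bad[1], " of query '", id, "'")
  }
  numbering_offset <- as.integer(numbering_offset)
  stopifnot(numbering_offset %in% c(0L, 1L))
  n_mature <- length(res) - numbering_offset
  if (is.null(core_range)) core_range <- c(1L, n_mature)
  core_range <- as.integer(core_range)
  if (length(core_range) != 2L || core_range[1] > core_range[2] ||
      core_range[1] < 1L || core_range[2] > n_mature) {
    stop("core_range must be an inclusive interval within mature positions 1..",
         n_mature)
  }
  structure(
    list(id = id, sequence = sequence, numbering_offset = numbering_offset,
         core_range = core_range),
    class = "hyb_query"
  )
}

#' @export
print.hyb_query <- function(x, ...) {
  cat("<hyb_query> ", x$id, ": ", nchar(x$sequence), " aa (numbering offset ",
      x$numbering_offset, ", core domain ", x$core_range[1], "-",
      x$core_range[2], ")\n", sep = "")
  invisible(x)
}

#' Read a protein query from FASTA
#'
#' Reads the first record of a protein FASTA file (or the record named by
#' `id`) into a [protein_query()].
#'
#' @param path FASTA file path.
#' @param id Optional record name to select; default: first record.
#' @inheritParams protein_query
#' @return A `hyb_query`.
#' @export
read_protein_query <- function(path, id = NULL, numbering_offset = 0L,
                               core_range = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(aa)) == id)
    if (!length(hit)) stop("no FASTA record named '", id, "' in ", path)
    aa <- aa[hit[1]]
  } else {
    aa <- aa[1]
  }
  protein_query(as.character(aa[[1]]), id = sub("\\s.*$", "", names(aa)),
                numbering_offset = numbering_offset, core_range = core_range)
}

#' Split a query into overlapping peptide windows
#'
#' Slides a window of `k` residues along the query with stride 1, yielding
#' all `L - k + 1` windows. These windows are the units that get
#' reverse-translated and matched against the genome; the 136-aa histone H3.2
#' query yields 129 windows at the default `k = 8`.
#'
#' @param query A `hyb_query` (or plain amino-acid string).
#' @param k Window length in residues.
#' @return A tibble with columns `index` (0-based start offset in the query),
#'   `peptide`, and `degeneracy` (product of per-residue codon degeneracies =
#'   number of DNA realizations of the window).
#' @export
make_windows <- function(query, k = 8L) {
  seq <- if (inherits(query, "hyb_query")) query$sequence else
    protein_query(query)$sequence
  k <- as.integer(k)
  L <- nchar(seq)
  if (k < 1L) stop("window length k must be >= 1")
  if (L < k) {
    stop("query length (", L, " aa) is shorter than the window length (",
         k, " aa)")
  }
  n <- L - k + 1L
  pep <- substring(seq, 1:n, k:L)
  deg <- codon_degeneracy(strsplit(seq, "")[[1]])
  prod_deg <- vapply(1:n, function(i) prod(deg[i:(i + k - 1L)]), numeric(1))
  tibble::tibble(index = 0:(n - 1L), peptide = pep, degeneracy = prod_deg)
}

#' Enumerate all DNA realizations of a peptide
#'
#' Expands a peptide into the Cartesian product of the synonymous codon sets
#' of its residues — every DNA sequence of length `3 * nchar(peptide)` whose
#' frame-0 translation equals the peptide.
#'
#' @param peptide Amino-acid string (one window).
#' @param code Genetic code tables.
#' @return Character vector of DNA strings, in lexicographic codon order.
#' @examples
#' reverse_translations("KC") # 2 x 2 = 4 sequences
#' @export
reverse_translations <- function(peptide, code = genetic_code()) {
  res <- strsplit(toupper(peptide), "")[[1]]
  bad <- which(!res %in% names(code$aa_to_codons))
  if (length(bad)) {
    stop("unknown amino-acid letter '", res[bad[1]], "' at position ", bad[1])
  }
  sets <- lapply(res, function(a) code$aa_to_codons[[a]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)[, length(sets):1,
                                                           drop = FALSE]
  do.call(paste0, grid)
}

#' Count reverse translations of a window set
#'
#' Closed-form count of DNA realizations across windows: the sum over windows
#' of the product of per-residue codon degeneracies. No enumeration is
#' performed. With `distinct = TRUE` the count collapses realizations shared
#' between windows; since two windows share a realization exactly when their
#' peptides are identical, the deduplicated total is the same sum taken over
#' *unique* window peptides.
#'
#' @param windows Tibble from [make_windows()] (or character vector of
#'   peptides).
#' @param code Genetic code tables.
#' @param distinct Count distinct DNA strings across windows instead of the
#'   raw per-window total.
#' @return A single number (double: totals can exceed integer range).
#' @export
count_reverse_translations <- function(windows, code = genetic_code(),
                                       distinct = FALSE) {
  pep <- if (is.character(windows)) windows else windows$peptide
  if (!length(pep)) stop("window set is empty")
  if (distinct) pep <- unique(pep)
  sum(vapply(
    pep,
    function(p) prod(codon_degeneracy(strsplit(p, "")[[1]], code)),
    numeric(1)
  ))
}

#' Write a window table as TSV
#'
#' @param windows Tibble from [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  readr::write_tsv(windows, path)
  invisible(path)
}
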