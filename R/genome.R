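#' Load a genome from FASTA
#'
#' Reads a multi-record FASTA into an upper-cased `DNAStringSet`. Record
#' names are truncated at the first whitespace and must be unique; only
#' A/C/G/T/N are accepted.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
load_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("no records in FASTA file: ", path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) {
    stop("duplicate record name(s) in ", path, ": ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  }
  dna <- Biostrings::DNAStringSet(toupper(dna))
  freq <- Biostrings::alphabetFrequency(dna)
  extra <- colSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
  if (any(extra > 0)) {
    offender <- names(extra)[extra > 0][1]
    rec <- which(rowSums(freq[, colnames(freq) == offender, drop = FALSE]) > 0)[1]
    pos <- as.integer(regexpr(offender, as.character(dna[[rec]]), fixed = TRUE))
    stop("non-A/C/G/T/N character '", offender, "' in record '",
         names(dna)[rec], "' at position ", pos)
  }
  dna
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(load_genome(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), window_index = integer(),
                 peptide = character())
}

sort_hits <- function(hits) {
  dplyr::arrange(hits, .data$chrom, .data$strand, .data$start,
                 .data$window_index)
}

#' Scan a genome for degenerate window matches
#'
#' Finds every position, on both strands, where a `3k`-nt genomic substring
#' is one of the synonymous-codon realizations of one of the query windows.
#' Implemented as a translate-and-lookup scan: each of the six frames is
#' translated and its k-mer peptides are tested for membership in the window
#' peptide set. Because the realizations of a window are *exactly* the DNA
#' strings whose frame-0 translation equals the window peptide, this is
#' equivalent to enumerating all realizations and exact-matching them
#' (see [oracle_scan()]), at a fraction of the cost.
#'
#' Codons overlapping an N translate to X and can never match, so no hit
#' overlaps an N. One hit is emitted per (position, strand, window); windows
#' with identical peptides yield one hit each at the same position.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @param windows Tibble from [make_windows()].
#' @param code Genetic code tables.
#' @return Tibble of hits: `chrom`, `start`, `end` (0-based half-open,
#'   `end - start == 3k`), `strand`, `window_index`, `peptide`.
#' @export
scan_genome <- function(genome, windows, code = genetic_code()) {
  genome <- as_genome(genome)
  k <- unique(nchar(windows$peptide))
  stopifnot(length(k) == 1L)
  pep_to_idx <- split(as.integer(windows$index), windows$peptide)
  peps <- names(pep_to_idx)
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- length(genome[[ci]])
    for (str in c("+", "-")) {
      s <- as.character(if (str == "+") genome[[ci]] else
        Biostrings::reverseComplement(genome[[ci]]))
      for (f in 0:2) {
        n_cod <- (L - f) %/% 3L
        if (n_cod < k) next
        prot <- frame_protein_chr(s, f)
        np <- nchar(prot) - k + 1L
        if (np < 1L) next
        kmers <- substring(prot, 1:np, k:(np + k - 1L))
        m <- match(kmers, peps)
        at <- which(!is.na(m))
        if (!length(at)) next
        ostart <- f + (at - 1L) * 3L # 0-based, strand-oriented
        idx_list <- pep_to_idx[m[at]]
        reps <- lengths(idx_list)
        ostart <- rep(ostart, reps)
        pep <- rep(peps[m[at]], reps)
        widx <- unlist(idx_list, use.names = FALSE)
        start <- if (str == "+") ostart else L - (ostart + 3L * k)
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom, start = as.integer(start),
          end = as.integer(start + 3L * k), strand = str,
          window_index = widx, peptide = pep
        )
      }
    }
  }
  if (!length(out)) return(empty_hits())
  sort_hits(dplyr::bind_rows(out))
}

#' Enumerate-and-match scan (reference implementation)
#'
#' The literal version of the screen: explicitly enumerates every DNA
#' realization of every window and exact-matches the full set against the
#' genome and its reverse complement (via [Biostrings::matchPDict()]). Used
#' as the independent oracle for [scan_genome()]; refuses to run when the
#' total enumeration exceeds `max_total`.
#'
#' @inheritParams scan_genome
#' @param max_total Cap on the total number of enumerated sequences.
#' @return Tibble of hits, identical in layout to [scan_genome()].
#' @export
oracle_scan <- function(genome, windows, code = genetic_code(),
                        max_total = 1e7) {
  genome <- as_genome(genome)
  total <- count_reverse_translations(windows, code)
  if (total > max_total) {
    stop("full enumeration would produce ", format(total, big.mark = ","),
         " sequences (cap ", format(max_total, big.mark = ","),
         "); use scan_genome() instead")
  }
  k <- unique(nchar(windows$peptide))
  stopifnot(length(k) == 1L)
  pep_to_idx <- split(as.integer(windows$index), windows$peptide)
  peps <- names(pep_to_idx)
  real_by_pep <- lapply(peps, reverse_translations, code = code)
  dict <- Biostrings::DNAStringSet(unlist(real_by_pep, use.names = FALSE))
  pat_pep <- rep(peps, lengths(real_by_pep)) # peptide of each pattern
  pd <- Biostrings::PDict(dict)
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- length(genome[[ci]])
    for (str in c("+", "-")) {
      s <- if (str == "+") genome[[ci]] else
        Biostrings::reverseComplement(genome[[ci]])
      m <- Biostrings::matchPDict(pd, s)
      nm <- S4Vectors::elementNROWS(m)
      if (!sum(nm)) next
      ir <- unlist(m)
      ostart <- BiocGenerics::start(ir) - 1L
      pep <- rep(pat_pep, nm)
      idx_list <- pep_to_idx[pep]
      reps <- lengths(idx_list)
      ostart <- rep(ostart, reps)
      pep <- rep(pep, reps)
      widx <- unlist(idx_list, use.names = FALSE)
      start <- if (str == "+") ostart else L - (ostart + 3L * k)
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = as.integer(start),
        end = as.integer(start + 3L * k), strand = str,
        window_index = widx, peptide = pep
      )
    }
  }
  if (!length(out)) return(empty_hits())
  sort_hits(dplyr::bind_rows(out))
}

#' Write hits as 6-column BED
#'
#' Name column is `window_index:peptide`, score 0; coordinates are 0-based
#' half-open as produced by [scan_genome()].
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- tibble::tibble(
    chrom = hits$chrom, start = hits$start, end = hits$end,
    name = paste0(hits$window_index, ":", hits$peptide),
    score = 0L, strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
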