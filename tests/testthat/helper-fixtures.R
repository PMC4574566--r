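aa_alphabet <- function() names(genetic_code()$aa_to_codons)

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random peptide whose full enumeration stays below `cap` realizations.
bounded_peptide <- function(len, cap = 2e5) {
  repeat {
    p <- random_protein(len)
    deg <- prod(codon_degeneracy(strsplit(p, "")[[1]]))
    if (deg <= cap) return(p)
  }
}

## Stop-bracketed implant cassette for a protein.
cassette_for <- function(protein) paste0("TAA", protein_to_cds(protein), "TAA")

## Independent edit-distance oracle: top-down recursion over edit scripts
## (memoized on suffix pair), structurally unlike the row-vectorized DP.
lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

## Manual hit rows for locus-merge tests (peptide doubles as identity).
hit_row <- function(start, peptide, chrom = "chr1", strand = "+", k = 8L,
                    window_index = 0L) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + 3L * k), strand = strand,
                 window_index = as.integer(window_index), peptide = peptide)
}

## Apply n substitutions to a protein, spaced at least `gap` residues apart.
spaced_variant <- function(protein, n, gap = 10L) {
  L <- nchar(protein)
  pos <- round(seq(gap, L - 2L, length.out = n))
  aa <- aa_alphabet()
  for (p in pos) {
    old <- substr(protein, p, p)
    substr(protein, p, p) <- sample(setdiff(aa, old), 1L)
  }
  protein
}
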