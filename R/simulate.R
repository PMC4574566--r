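#' Randomly recode a CDS with synonymous codons
#'
#' Each codon is independently replaced, with probability `rate`, by a codon
#' drawn uniformly from its synonymous set. The encoded protein is unchanged
#' by construction and no stop codon can be introduced. This is the
#' divergence mode the degenerate screen is designed to see through.
#'
#' @param cds DNA string, length divisible by 3, no internal stop codons.
#' @param rate Per-codon recoding probability in `[0, 1]`.
#' @param code Genetic code tables.
#' @param seed Optional seed for reproducibility of this call.
#' @return Recoded DNA string of the same length.
#' @export
recode_synonymous <- function(cds, rate = 1, code = genetic_code(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (0:(n - 1L)) + 1L, 3L * (1:n))
  aa <- unname(code$codon_to_aa[codons])
  if (anyNA(aa)) stop("invalid codon in CDS: ", codons[which(is.na(aa))[1]])
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  swap <- stats::runif(n) < rate
  codons[swap] <- vapply(aa[swap], function(a) {
    s <- code$aa_to_codons[[a]]
    s[sample.int(length(s), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Disrupt a CDS with a single-base frameshift
#'
#' Deletes (`indel = -1`) the base at `position`, or inserts (`indel = +1`)
#' `base` before `position`, shifting the downstream reading frame — the
#' defining lesion of a frameshift pseudogene.
#'
#' @param cds DNA string.
#' @param position 1-based position of the indel, strictly inside the CDS.
#' @param indel `-1` (deletion) or `+1` (insertion).
#' @param base Base to insert when `indel = +1`.
#' @return Disrupted DNA string.
#' @export
make_frameshift_pseudogene <- function(cds, position, indel = -1L,
                                       base = "A") {
  n <- nchar(cds)
  if (!(position > 0L && position < n)) {
    stop("indel position must lie strictly inside the CDS (1 < ", position,
         " < ", n, " fails)")
  }
  if (indel == -1L) {
    paste0(substr(cds, 1L, position - 1L), substr(cds, position + 1L, n))
  } else if (indel == 1L) {
    paste0(substr(cds, 1L, position - 1L), base, substr(cds, position, n))
  } else {
    stop("indel must be -1 or +1")
  }
}

.CANONICAL_STEM_LOOP <- "GGCTCTTTTCAGAGCC"

#' Implant specifications for a synthetic genome
#'
#' One row per element to implant. `kind` is one of `exact_cds`,
#' `recoded_cds`, `substituted_variant`, `frameshift_pseudogene`,
#' `truncated_fragment`; `three_prime` is `polyA`, `stemloop` or `none`.
#' Unused parameter columns are `NA`.
#'
#' @param kind,strand,three_prime Character vectors (recycled).
#' @param n_subs Substitution count (substituted_variant).
#' @param recode_rate Per-codon recoding rate (recoded_cds).
#' @param fs_codon,indel Frameshift codon (1-based, in the full protein) and
#'   indel direction (frameshift_pseudogene).
#' @param frag_start,frag_len Fragment start (1-based residue in the full
#'   query) and length (truncated_fragment).
#' @param chrom,offset Optional explicit placement (0-based offset of the
#'   implant slot); `NA` = automatic non-overlapping placement.
#' @param id Element ids; default `imp_01`, ...
#' @return Tibble of implant specs for [simulate_genome()].
#' @export
implant_spec <- function(kind, strand = "+", three_prime = "none",
                         n_subs = NA_integer_, recode_rate = NA_real_,
                         fs_codon = NA_integer_, indel = NA_integer_,
                         frag_start = NA_integer_, frag_len = NA_integer_,
                         chrom = NA_character_, offset = NA_integer_,
                         id = NULL) {
  out <- tibble::tibble(kind = kind, strand = strand,
                        three_prime = three_prime, n_subs = n_subs,
                        recode_rate = recode_rate, fs_codon = fs_codon,
                        indel = indel, frag_start = frag_start,
                        frag_len = frag_len, chrom = chrom, offset = offset)
  bad_kind <- !out$kind %in% c("exact_cds", "recoded_cds",
                               "substituted_variant",
                               "frameshift_pseudogene", "truncated_fragment")
  if (any(bad_kind)) stop("unknown implant kind: ", out$kind[bad_kind][1])
  if (is.null(id)) id <- sprintf("imp_%02d", seq_len(nrow(out)))
  dplyr::mutate(out, id = id, .before = 1L)
}

#' The default 20-element demo implant set
#'
#' A mixed panel exercising every element kind under study-like conditions:
#' exact and synonymously recoded copies of the query CDS (detectable, PASS),
#' amino-acid-substituted variants with substitutions spaced to preserve
#' conserved runs (detectable, PASS), frameshift pseudogenes broken upstream
#' of or inside the core domain (CORE_OUT_OF_FRAME), and truncated fragments
#' — sub-10-aa ones (TOO_SHORT), a core-covering one (PASS) and an
#' N-terminal-only one (CORE_OUT_OF_FRAME) — across both strands and all
#' three 3'-end structures.
#'
#' @return An [implant_spec()] tibble with 20 rows.
#' @export
demo_implants <- function() {
  implant_spec(
    kind = c(rep("exact_cds", 4), rep("recoded_cds", 5),
             rep("substituted_variant", 4),
             rep("frameshift_pseudogene", 3),
             rep("truncated_fragment", 4)),
    strand = c("+", "-", "+", "-",
               "+", "-", "+", "-", "+",
               "+", "-", "+", "-",
               "+", "-", "+",
               "+", "-", "+", "-"),
    three_prime = c("stemloop", "polyA", "none", "polyA",
                    "polyA", "stemloop", "none", "polyA", "stemloop",
                    "polyA", "polyA", "stemloop", "none",
                    "none", "polyA", "none",
                    "none", "none", "polyA", "none"),
    recode_rate = c(rep(NA, 4), 1, 0.7, 0.5, 0.3, 1, rep(NA, 11)),
    n_subs = c(rep(NA, 9), 2, 3, 5, 8, rep(NA, 7)),
    fs_codon = c(rep(NA, 13), 30, 75, 110, rep(NA, 4)),
    indel = c(rep(NA, 13), -1, 1, -1, rep(NA, 4)),
    frag_start = c(rep(NA, 16), 2, 5, 50, 1),
    frag_len = c(rep(NA, 16), 9, 9, 87, 30)
  )
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Break any polyA signal / stem-loop in an oriented sequence by point
## mutation (used to screen simulated downstream regions). `prefix` is
## immutable upstream context (the cassette's closing stop codon) included
## in the search so boundary-spanning motifs are also removed.
screen_motifs <- function(seq, loop_pattern = "^TT[TC]", prefix = "") {
  np <- nchar(prefix)
  for (iter in 1:100) {
    s <- paste0(prefix, seq)
    pa <- as.integer(regexpr("AATAAA|ATTAAA", s))
    sl <- find_stem_loop(s, loop_pattern)
    if (pa < 0L && is.na(sl)) return(seq)
    if (pa > 0L) {
      q <- max(pa + 2L, np + 1L) - np # position within seq
      substr(seq, q, q) <- "C"
    }
    if (!is.na(sl)) {
      q <- sl + 12L - np # inside the 3' stem arm, always past the prefix
      substr(seq, q, q) <- if (substr(seq, q, q) == "A") "C" else "A"
    }
  }
  stop("could not screen motifs out of simulated sequence")
}

## Longest run of query-identical residues (full-sequence indexing) given
## substituted positions; detectability needs a run of >= k + 1.
longest_clean_run <- function(total_len, changed_pos) {
  bounds <- c(0L, sort(changed_pos), total_len + 1L)
  max(diff(bounds) - 1L)
}

#' Simulate a genome with implanted query-derived elements
#'
#' Generates i.i.d. background chromosomes at the requested GC content and
#' implants each element as a stop-bracketed cassette (`TAA` + CDS + `TAA`,
#' reverse-complemented on the minus strand) followed by an 800-nt
#' downstream region carrying the requested 3'-end motif (canonical histone
#' stem-loop 16-mer or AATAAA) and screened free of competing motifs. After
#' assembly the whole genome is screened for chance loci: any merged locus
#' outside the truth intervals has its background bases resampled. The
#' result is byte-reproducible for a fixed seed.
#'
#' @param implants [implant_spec()] tibble.
#' @param seed Mandatory random seed.
#' @param query The `hyb_query` the elements derive from.
#' @param chrom_lengths Named chromosome lengths.
#' @param gc Background GC fraction.
#' @param k Window length the screen will use (sets the detectability rule
#'   and the spurious-locus screen).
#' @param downstream_span Reserved oriented downstream span per implant.
#' @return A `hyb_simulation`: list with `genome` (DNAStringSet), `truth`
#'   (tibble: `id`, `kind`, `chrom`, `strand`, `cds_start`, `cds_end`,
#'   `protein`, `expected_detectable`, `expected_flag`,
#'   `expected_three_prime`), and `manifest` (parameters and seed).
#' @export
simulate_genome <- function(implants, seed, query = h3_query(),
                            chrom_lengths = c(chrA = 30000L, chrB = 30000L),
                            gc = 0.42, k = 8L, downstream_span = 800L) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  stopifnot(!is.null(names(chrom_lengths)))
  full_prot <- query$sequence
  full_len <- nchar(full_prot)
  off <- query$numbering_offset
  core_lo_full <- query$core_range[1] + off # 1-based in full sequence
  core_hi_full <- query$core_range[2] + off
  chroms <- lapply(chrom_lengths, random_dna, gc = gc)

  margin <- 120L
  cursor <- stats::setNames(rep(margin, length(chrom_lengths)),
                            names(chrom_lengths))
  truth <- list()
  slots <- list()
  aa_letters <- names(genetic_code()$aa_to_codons)

  for (i in seq_len(nrow(implants))) {
    im <- implants[i, ]
    prot <- full_prot
    changed <- integer(0)
    protein_out <- NA_character_
    disrupted <- FALSE
    if (im$kind == "truncated_fragment") {
      fe <- im$frag_start + im$frag_len - 1L
      stopifnot(im$frag_start >= 1L, fe <= full_len)
      prot <- substr(full_prot, im$frag_start, fe)
    } else if (im$kind == "substituted_variant") {
      # spaced substitutions: keep every clean run >= k + 1 residues
      gap <- max(k + 2L, full_len %/% (im$n_subs + 1L))
      pos <- round(seq(gap, full_len - k - 1L, length.out = im$n_subs))
      for (p in pos) {
        old <- substr(prot, p, p)
        substr(prot, p, p) <- sample(setdiff(aa_letters, old), 1L)
      }
      changed <- as.integer(pos)
    }
    cds <- protein_to_cds(prot)
    if (im$kind == "recoded_cds") cds <- recode_synonymous(cds, im$recode_rate)
    if (im$kind == "frameshift_pseudogene") {
      stopifnot(im$fs_codon > k + 1L, im$fs_codon < full_len)
      cds <- make_frameshift_pseudogene(cds, 3L * (im$fs_codon - 1L) + 2L,
                                        indel = im$indel)
      disrupted <- TRUE
      protein_out <- paste0("frameshift@codon", im$fs_codon)
    } else {
      protein_out <- prot
    }
    cassette <- paste0("TAA", cds, "TAA")
    slot_len <- nchar(cassette) + downstream_span + margin

    chrom <- im$chrom
    if (is.na(chrom)) {
      fits <- names(chrom_lengths)[cursor + slot_len <=
                                     chrom_lengths - margin]
      if (!length(fits)) stop("implants do not fit in the genome")
      chrom <- fits[1]
    }
    slot_start <- if (is.na(im$offset)) cursor[[chrom]] else im$offset
    slot_end <- slot_start + slot_len
    if (slot_end > chrom_lengths[[chrom]]) {
      stop("implant ", im$id, " does not fit on ", chrom)
    }
    for (s in slots) {
      if (s$chrom == chrom && slot_start < s$end && s$start < slot_end) {
        stop("implant ", im$id, " overlaps implant ", s$id)
      }
    }
    slots[[length(slots) + 1L]] <- list(id = im$id, chrom = chrom,
                                        start = slot_start, end = slot_end)
    cursor[[chrom]] <- max(cursor[[chrom]], slot_end)

    # oriented layout within the slot: cassette then downstream span
    if (im$strand == "+") {
      cass_start <- slot_start
      down_start <- cass_start + nchar(cassette)
      down_seq <- substr(chroms[[chrom]], down_start + 1L,
                         down_start + downstream_span)
    } else {
      down_start <- slot_start
      cass_start <- down_start + downstream_span
      down_seq <- revcomp_chr(substr(chroms[[chrom]], down_start + 1L,
                                     down_start + downstream_span))
    }
    down_seq <- screen_motifs(down_seq, prefix = "TAA")
    if (im$three_prime == "polyA") {
      substr(down_seq, 21L, 26L) <- "AATAAA"
    } else if (im$three_prime == "stemloop") {
      substr(down_seq, 21L, 36L) <- .CANONICAL_STEM_LOOP
    }
    if (im$strand == "-") down_seq <- revcomp_chr(down_seq)
    substr(chroms[[chrom]], down_start + 1L,
           down_start + downstream_span) <- down_seq
    ins <- if (im$strand == "+") cassette else revcomp_chr(cassette)
    substr(chroms[[chrom]], cass_start + 1L,
           cass_start + nchar(cassette)) <- ins

    # truth coordinates of the CDS proper (brackets excluded), genomic
    if (im$strand == "+") {
      cds_start <- cass_start + 3L
      cds_end <- cds_start + nchar(cds)
    } else {
      cds_end <- cass_start + nchar(cassette) - 3L
      cds_start <- cds_end - nchar(cds)
    }
    detectable <- switch(
      im$kind,
      exact_cds = , recoded_cds = TRUE,
      substituted_variant = longest_clean_run(full_len, changed) >= k + 1L,
      frameshift_pseudogene = max(im$fs_codon - 1L,
                                  full_len - im$fs_codon) >= k + 1L,
      truncated_fragment = im$frag_len >= k + 1L
    )
    flag <- switch(
      im$kind,
      exact_cds = , recoded_cds = , substituted_variant = "PASS",
      frameshift_pseudogene =
        if (im$fs_codon <= core_hi_full) "CORE_OUT_OF_FRAME" else "PASS",
      truncated_fragment =
        if (im$frag_len < 10L) "TOO_SHORT"
        else if (im$frag_start <= core_lo_full &&
                 im$frag_start + im$frag_len - 1L >= core_hi_full) "PASS"
        else "CORE_OUT_OF_FRAME"
    )
    truth[[i]] <- tibble::tibble(
      id = im$id, kind = im$kind, chrom = chrom, strand = im$strand,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      protein = protein_out,
      expected_detectable = detectable,
      expected_flag = flag,
      expected_three_prime = switch(im$three_prime, polyA = "PolyA",
                                    stemloop = "StemLoop", "NotDetected")
    )
  }
  truth <- dplyr::bind_rows(truth)
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- names(chrom_lengths)

  # spurious-locus screen: resample background under any chance locus
  windows <- make_windows(query, k = k)
  slot_tbl <- dplyr::bind_rows(lapply(slots, tibble::as_tibble))
  for (iter in 1:5) {
    loci <- merge_hits(scan_genome(genome, windows))
    spurious <- loci |>
      dplyr::filter(!purrr::pmap_lgl(
        list(.data$chrom, .data$start, .data$end),
        function(ch, s, e) any(slot_tbl$chrom == ch & s < slot_tbl$end &
                                 slot_tbl$start < e)
      ))
    if (nrow(spurious) == 0L) break
    chroms <- stats::setNames(as.character(genome), names(genome))
    for (j in seq_len(nrow(spurious))) {
      ch <- spurious$chrom[j]
      s <- spurious$start[j]; e <- spurious$end[j]
      inside_slot <- any(slot_tbl$chrom == ch & slot_tbl$start <= s &
                           e <= slot_tbl$end)
      if (inside_slot) next
      substr(chroms[[ch]], s + 1L, e) <- random_dna(e - s, gc = gc)
    }
    genome <- Biostrings::DNAStringSet(chroms)
  }

  structure(list(
    genome = genome, truth = truth, query = query,
    manifest = list(seed = seed, k = k, gc = gc,
                    chrom_lengths = as.list(chrom_lengths),
                    downstream_span = downstream_span,
                    n_implants = nrow(implants),
                    implants = implants)
  ), class = "hyb_simulation")
}

#' @export
print.hyb_simulation <- function(x, ...) {
  cat("<hyb_simulation> ", length(x$genome), " chromosome(s), ",
      sum(lengths(x$genome)), " nt, ", nrow(x$truth),
      " implanted element(s) (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Writes `genome.fa`, `truth.tsv`, `truth.gff3` and `manifest.json` into
#' `dir`. Re-running with the same seed reproduces the files byte for byte.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"),
                              width = 70L)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  gr <- GenomicRanges::GRanges(
    sim$truth$chrom,
    IRanges::IRanges(sim$truth$cds_start + 1L, sim$truth$cds_end),
    strand = sim$truth$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "CDS", phase = 0L, ID = sim$truth$id, kind = sim$truth$kind,
    expected_flag = sim$truth$expected_flag
  )
  rtracklayer::export(gr, file.path(dir, "truth.gff3"), format = "gff3")
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
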