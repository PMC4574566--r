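#' Merge nearby hits into candidate loci
#'
#' Single-linkage chaining per chromosome and strand: consecutive hits whose
#' end-to-start gap is at most `max_gap` nt join the same locus (so a chain
#' of hits each within `max_gap` of its neighbour forms one locus even when
#' the first and last are far apart). Loci supported by fewer than
#' `min_distinct` distinct window peptides are discarded — an isolated hit is
#' never reported. Emitted loci are maximal: two loci on the same chromosome
#' and strand are always separated by more than `max_gap` nt.
#'
#' @param hits Hit tibble from [scan_genome()].
#' @param max_gap Maximum end-to-start gap (nt) between consecutive member
#'   hits (inclusive threshold).
#' @param min_distinct Minimum number of distinct window peptides per locus.
#' @return Tibble of loci: `locus_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span of all member hits), `n_hits`,
#'   `n_distinct_windows`, and a nested `hits` list-column.
#' @export
merge_hits <- function(hits, max_gap = 90L, min_distinct = 2L) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(locus_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), n_hits = integer(),
                          n_distinct_windows = integer(), hits = list()))
  }
  loci <- hits |>
    sort_hits() |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(
      .reach = cummax(.data$end),
      .new = .data$start - dplyr::lag(.data$.reach,
                                      default = dplyr::first(.data$start)) > max_gap,
      .cluster = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$.cluster) |>
    tidyr::nest(hits = c(-"chrom", -"strand", -".cluster")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      hits = purrr::map(.data$hits, ~ dplyr::select(.x, -".reach", -".new")),
      start = purrr::map_int(.data$hits, ~ min(.x$start)),
      end = purrr::map_int(.data$hits, ~ max(.x$end)),
      n_hits = purrr::map_int(.data$hits, nrow),
      n_distinct_windows = purrr::map_int(.data$hits,
                                          ~ dplyr::n_distinct(.x$peptide))
    ) |>
    dplyr::filter(.data$n_distinct_windows >= min_distinct) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start)
  loci |>
    dplyr::mutate(locus_id = sprintf("locus_%03d", dplyr::row_number())) |>
    dplyr::select("locus_id", "chrom", "strand", "start", "end", "n_hits",
                  "n_distinct_windows", "hits")
}

## Translate one strand-oriented frame of a chromosome, with caching.
## Returns list(prot = translated string, stops = 0-based codon indices of
## stop codons, n_cod = number of codons).
frame_translation <- function(cache, genome, chrom, str, frame) {
  key <- paste(chrom, str, frame, sep = "\r")
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  s <- as.character(if (str == "+") genome[[chrom]] else
    Biostrings::reverseComplement(genome[[chrom]]))
  n_cod <- (nchar(s) - frame) %/% 3L
  prot <- frame_protein_chr(s, frame)
  val <- list(prot = prot,
              stops = which(strsplit(prot, "")[[1]] == "*") - 1L,
              n_cod = n_cod)
  cache[[key]] <- val
  val
}

#' Reconstruct ORFs for candidate loci
#'
#' For each locus the member hits vote on a dominant reading frame (majority
#' of hits; ties broken in favour of the anchor — the most N-terminal matched
#' window). The ORF is the maximal stop-to-stop stretch in that frame that
#' best covers the member hits, strand-aware; the predicted protein is its
#' translation (no ATG requirement unless `require_atg = TRUE`).
#'
#' The core-domain frame check is anchored at the most N-terminal hit: the
#' core is covered in frame when (i) every hit overlapping the query
#' core-domain range shares the anchor hit's alignment offset, and (ii) the
#' anchor-frame translation from the anchor through the projected core end
#' contains no stop codon and stays within the contig. A frameshift upstream
#' of (or inside) the core breaks (i); a premature stop breaks (ii); a locus
#' truncated at a contig edge before the core end fails the check and is
#' flagged truncated.
#'
#' @param loci Locus tibble from [merge_hits()].
#' @param genome Genome as in [scan_genome()].
#' @param query The `hyb_query` the windows came from (supplies numbering
#'   offset and core-domain range).
#' @param require_atg Trim the ORF to its first ATG (drop loci without one).
#' @return `loci` with added columns `orf_start`, `orf_end` (genomic, 0-based
#'   half-open), `frame_offset`, `protein`, `protein_length`,
#'   `has_internal_stop`, `core_covered_in_frame`, `truncated`.
#' @export
reconstruct_orfs <- function(loci, genome, query, require_atg = FALSE) {
  genome <- as_genome(genome)
  cache <- new.env(parent = emptyenv())
  if (nrow(loci) == 0L) {
    return(dplyr::mutate(loci, orf_start = integer(), orf_end = integer(),
                         frame_offset = integer(), protein = character(),
                         protein_length = integer(),
                         has_internal_stop = logical(),
                         core_covered_in_frame = logical(),
                         truncated = logical()))
  }
  k <- nchar(loci$hits[[1]]$peptide[1])
  off <- query$numbering_offset
  core_lo_idx <- query$core_range[1] + off - 1L # 0-based residue index
  core_hi_idx <- query$core_range[2] + off - 1L
  one <- function(chrom, str, hits) {
    L <- length(genome[[chrom]])
    o_start <- if (str == "+") hits$start else L - hits$end
    offset <- o_start - 3L * hits$window_index
    ord <- order(hits$window_index, o_start)
    anchor_offset <- offset[ord[1]]
    anchor_ostart <- o_start[ord[1]]
    tab <- table(offset)
    best <- as.integer(names(tab)[tab == max(tab)])
    dom_offset <- if (anchor_offset %in% best) anchor_offset else min(best)
    dom_frame <- ((dom_offset %% 3L) + 3L) %% 3L
    ft <- frame_translation(cache, genome, chrom, str, dom_frame)
    in_dom <- ((offset - dom_frame) %% 3L) == 0L
    c_lo <- (min(o_start[in_dom]) - dom_frame) %/% 3L
    c_hi <- (max(o_start[in_dom] + 3L * k) - dom_frame) %/% 3L - 1L
    # stop-free stretches in the dominant frame, pick max overlap with hits
    bounds <- c(-1L, ft$stops, ft$n_cod)
    st_lo <- utils::head(bounds, -1L) + 1L
    st_hi <- utils::tail(bounds, -1L) - 1L
    keep <- st_lo <= st_hi
    st_lo <- st_lo[keep]; st_hi <- st_hi[keep]
    ov <- pmin(st_hi, c_hi) - pmax(st_lo, c_lo) + 1L
    pick <- which.max(ov) # leftmost maximal
    a <- st_lo[pick]; b <- st_hi[pick]
    truncated <- (a == 0L && !((a - 1L) %in% ft$stops)) ||
      (b == ft$n_cod - 1L && !((b + 1L) %in% ft$stops))
    protein <- substr(ft$prot, a + 1L, b + 1L)
    orf_a <- a; orf_b <- b
    if (require_atg) {
      m <- regexpr("M", protein, fixed = TRUE)
      if (m < 0L) {
        protein <- ""
      } else {
        orf_a <- a + as.integer(m) - 1L
        protein <- substr(protein, as.integer(m), nchar(protein))
      }
    }
    orf_ostart <- dom_frame + 3L * orf_a
    orf_oend <- dom_frame + 3L * (orf_b + 1L)
    has_internal_stop <- any(ft$stops >= c_lo & ft$stops <= c_hi)
    # --- core-domain frame check, anchored at the most N-terminal hit ---
    anchor_frame <- ((anchor_offset %% 3L) + 3L) %% 3L
    core_hits <- hits$window_index <= core_hi_idx &
      hits$window_index + k - 1L >= core_lo_idx
    frames_ok <- all(offset[core_hits] == anchor_offset)
    g_core_start <- anchor_offset + 3L * core_lo_idx
    g_core_end <- anchor_offset + 3L * (core_hi_idx + 1L)
    core_truncated <- g_core_start < 0L || g_core_end > L
    core_covered <- frames_ok && !core_truncated
    if (core_covered) {
      fa <- if (anchor_frame == dom_frame) ft else
        frame_translation(cache, genome, chrom, str, anchor_frame)
      lo_cod <- min((anchor_ostart - anchor_frame) %/% 3L,
                    (g_core_start - anchor_frame) %/% 3L)
      hi_cod <- (g_core_end - anchor_frame) %/% 3L - 1L
      core_covered <- !any(fa$stops >= lo_cod & fa$stops <= hi_cod)
    }
    gs <- if (str == "+") orf_ostart else L - orf_oend
    ge <- if (str == "+") orf_oend else L - orf_ostart
    tibble::tibble(orf_start = as.integer(gs), orf_end = as.integer(ge),
                   frame_offset = as.integer(dom_offset),
                   protein = protein, protein_length = nchar(protein),
                   has_internal_stop = has_internal_stop,
                   core_covered_in_frame = core_covered,
                   truncated = truncated || core_truncated)
  }
  extra <- purrr::pmap(list(loci$chrom, loci$strand, loci$hits), one) |>
    dplyr::bind_rows()
  dplyr::bind_cols(loci, extra)
}

#' Apply peptide-length and core-domain filters
#'
#' A locus passes when its predicted peptide is at least `min_peptide_len`
#' residues long *and* the query core domain is covered in a single
#' uninterrupted reading frame (see [reconstruct_orfs()]). Every rejection
#' carries a flag: `TOO_SHORT`, `CORE_OUT_OF_FRAME`, or both.
#'
#' @param loci Locus tibble from [reconstruct_orfs()].
#' @param min_peptide_len Minimum predicted peptide length (aa).
#' @return `loci` with added columns `too_short`, `core_out_of_frame`,
#'   `pass`, and `filter_flags` (comma-joined, `"PASS"` when passing).
#' @export
apply_filters <- function(loci, min_peptide_len = 10L) {
  loci |>
    dplyr::mutate(
      too_short = .data$protein_length < min_peptide_len,
      core_out_of_frame = !.data$core_covered_in_frame,
      pass = !.data$too_short & !.data$core_out_of_frame,
      filter_flags = dplyr::case_when(
        .data$pass ~ "PASS",
        .data$too_short & .data$core_out_of_frame ~ "TOO_SHORT,CORE_OUT_OF_FRAME",
        .data$too_short ~ "TOO_SHORT",
        TRUE ~ "CORE_OUT_OF_FRAME"
      )
    )
}

#' Export candidate loci as GFF3
#'
#' Writes one `gene` feature per locus with the predicted protein and filter
#' flags in the attributes column.
#'
#' @param loci Filtered locus tibble ([apply_filters()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = loci$locus_id,
    filter_flags = loci$filter_flags,
    protein = loci$protein
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export candidate loci as TSV (1-based inclusive coordinates)
#'
#' Human-facing report: locus coordinates in 1-based inclusive convention,
#' predicted protein, filter flags, and a 3'-end structure column when
#' present.
#'
#' @inheritParams write_candidates_gff3
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(loci, path) {
  out <- loci |>
    dplyr::mutate(start = .data$start + 1L) |>
    dplyr::select(-dplyr::any_of("hits"))
  readr::write_tsv(out, path)
  invisible(path)
}
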