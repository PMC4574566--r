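#' Read gene models (refFlat or GTF)
#'
#' Imports transcript models into a uniform tibble with 0-based half-open
#' intervals. refFlat (UCSC dialect: geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) is natively
#' 0-based half-open and is taken as-is; GTF (1-based inclusive) is converted
#' on import, with exon and CDS features grouped per transcript.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"refflat"`, or `"gtf"`.
#' @return Tibble with columns `gene`, `transcript`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, and list-columns
#'   `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path, format = c("auto", "refflat", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
      else "refflat"
  }
  if (format == "refflat") read_refflat(path) else read_gtf_models(path)
}

read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_ok <- lengths(fields) >= 11L
  if (any(!n_ok)) {
    stop("malformed refFlat line ", which(!n_ok)[1], " in ", path,
         ": expected 11 tab-separated fields, got ", lengths(fields)[!n_ok][1])
  }
  parse_one <- function(f, i) {
    starts <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    ends <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    n_exon <- as.integer(f[9])
    if (length(starts) != n_exon || length(ends) != n_exon) {
      stop("malformed refFlat line ", i, " in ", path,
           ": exonCount=", n_exon, " but ", length(starts), " exonStarts / ",
           length(ends), " exonEnds")
    }
    if (is.unsorted(starts) || any(ends <= starts)) {
      stop("malformed refFlat line ", i, " in ", path,
           ": exons must be sorted, non-empty intervals")
    }
    tibble::tibble(gene = f[1], transcript = f[2], chrom = f[3],
                   strand = f[4], tx_start = as.integer(f[5]),
                   tx_end = as.integer(f[6]), cds_start = as.integer(f[7]),
                   cds_end = as.integer(f[8]), exon_starts = list(starts),
                   exon_ends = list(ends))
  }
  dplyr::bind_rows(purrr::imap(fields, parse_one))
}

read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  tx <- as.character(md$transcript_id)
  gene <- as.character(md$gene_id)
  if (!is.null(md$gene_name)) {
    gn <- as.character(md$gene_name)
    gene <- ifelse(is.na(gn) | gn == "", gene, gn)
  }
  type <- as.character(md$type)
  df <- tibble::tibble(
    gene = gene, transcript = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L, # to 0-based half-open
    end = BiocGenerics::end(gr), type = type
  )
  ex <- dplyr::filter(df, .data$type == "exon")
  if (nrow(ex) == 0L) stop("no exon features in GTF file: ", path)
  cds <- dplyr::filter(df, .data$type == "CDS")
  cds_rng <- cds |>
    dplyr::group_by(.data$transcript) |>
    dplyr::summarise(cds_start = min(.data$start), cds_end = max(.data$end))
  ex |>
    dplyr::arrange(.data$transcript, .data$start) |>
    dplyr::group_by(.data$gene, .data$transcript, .data$chrom, .data$strand) |>
    dplyr::summarise(tx_start = min(.data$start), tx_end = max(.data$end),
                     exon_starts = list(.data$start),
                     exon_ends = list(.data$end), .groups = "drop") |>
    dplyr::left_join(cds_rng, by = "transcript") |>
    dplyr::mutate(
      cds_start = dplyr::coalesce(.data$cds_start, .data$tx_end),
      cds_end = dplyr::coalesce(.data$cds_end, .data$tx_end)
    ) |>
    dplyr::select("gene", "transcript", "chrom", "strand", "tx_start",
                  "tx_end", "cds_start", "cds_end", "exon_starts",
                  "exon_ends") |>
    dplyr::arrange(.data$chrom, .data$tx_start)
}

models_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$tx_start + 1L,
                              end = models$tx_end),
    strand = models$strand
  )
}

#' Label candidate loci against gene annotations
#'
#' Assigns each locus one label by precedence known > pseudogene >
#' predicted > unannotated: overlap with a curated gene gives `known`,
#' overlap with a pseudogene-patterned model gives `pseudogene`, overlap
#' with a predicted-only model (default name prefix `Gm`) gives `predicted`,
#' otherwise `unannotated`.
#'
#' @param loci Locus tibble (needs `chrom`, `start`, `end`).
#' @param models Gene-model tibble from [read_gene_models()].
#' @param predicted_pattern Regex on gene names marking predicted-only models.
#' @param pseudogene_pattern Regex on gene names marking pseudogene models.
#' @return `loci` with an added `annotation` column.
#' @export
label_candidates <- function(loci, models, predicted_pattern = "^Gm",
                             pseudogene_pattern = "-ps") {
  if (nrow(loci) == 0L) return(dplyr::mutate(loci, annotation = character()))
  cls <- dplyr::case_when(
    grepl(pseudogene_pattern, models$gene) ~ "pseudogene",
    grepl(predicted_pattern, models$gene) ~ "predicted",
    TRUE ~ "known"
  )
  lr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  mr <- models_granges(models)
  ov <- GenomicRanges::findOverlaps(lr, mr, ignore.strand = TRUE)
  lab <- rep("unannotated", nrow(loci))
  rank <- c(known = 1, pseudogene = 2, predicted = 3)
  if (length(ov)) {
    hit_cls <- cls[S4Vectors::subjectHits(ov)]
    best <- tapply(rank[hit_cls], S4Vectors::queryHits(ov), min)
    lab[as.integer(names(best))] <- names(rank)[best]
  }
  dplyr::mutate(loci, annotation = lab)
}

#' Build a promoter / gene-body / intergenic category map
#'
#' Promoters are the union of TSS +/- `promoter_halfwidth` windows (half-open,
#' width `2 * promoter_halfwidth`), clipped to chromosome ends; gene bodies
#' are the union of transcript spans minus promoters (promoter takes
#' precedence); everything else is intergenic.
#'
#' @param models Gene-model tibble.
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @param promoter_halfwidth Promoter half-width in nt.
#' @return A `hyb_category_map`: list with GRanges `promoter`, `gene_body`
#'   and the chromosome lengths.
#' @export
category_map <- function(models, genome_lengths, promoter_halfwidth = 2000L) {
  stopifnot(!is.null(names(genome_lengths)))
  clip <- function(gr) {
    lens <- genome_lengths[as.character(GenomicRanges::seqnames(gr))]
    over <- BiocGenerics::end(gr) > lens | BiocGenerics::start(gr) < 1L
    if (any(over)) warning(sum(over), " interval(s) clipped to chromosome ends")
    BiocGenerics::start(gr) <- pmax(BiocGenerics::start(gr), 1L)
    BiocGenerics::end(gr) <- pmin(BiocGenerics::end(gr), lens)
    gr[BiocGenerics::width(gr) > 0L]
  }
  if (nrow(models)) {
    tss <- ifelse(models$strand == "+", models$tx_start, models$tx_end - 1L)
    prom <- GenomicRanges::GRanges(
      models$chrom,
      IRanges::IRanges(start = tss - promoter_halfwidth + 1L,
                       end = tss + promoter_halfwidth)
    )
    prom <- GenomicRanges::reduce(clip(prom), ignore.strand = TRUE)
    body <- GenomicRanges::reduce(clip(models_granges(models)),
                                  ignore.strand = TRUE)
    body <- GenomicRanges::setdiff(body, prom, ignore.strand = TRUE)
  } else {
    prom <- GenomicRanges::GRanges()
    body <- GenomicRanges::GRanges()
  }
  structure(list(promoter = prom, gene_body = body,
                 genome_lengths = genome_lengths,
                 promoter_halfwidth = promoter_halfwidth),
            class = "hyb_category_map")
}

#' Genome fractions of promoter / gene body / intergenic bases
#'
#' Fractions (percent) of the effective genome length occupied by each
#' category; intergenic is the remainder, so the three always sum to 100.
#'
#' @inheritParams category_map
#' @param effective_length Effective genome length used as denominator;
#'   default: sum of the chromosome lengths.
#' @return Tibble with columns `category`, `bases`, `fraction` (percent).
#' @export
genome_category_fractions <- function(models, genome_lengths,
                                      promoter_halfwidth = 2000L,
                                      effective_length = NULL) {
  cm <- if (inherits(models, "hyb_category_map")) models else
    category_map(models, genome_lengths, promoter_halfwidth)
  if (is.null(effective_length)) {
    effective_length <- sum(as.numeric(cm$genome_lengths))
  }
  p <- sum(as.numeric(BiocGenerics::width(cm$promoter)))
  g <- sum(as.numeric(BiocGenerics::width(cm$gene_body)))
  tibble::tibble(
    category = c("promoter", "gene_body", "intergenic"),
    bases = c(p, g, effective_length - p - g),
    fraction = 100 * .data$bases / effective_length
  )
}

as_intervals <- function(x) {
  if (inherits(x, "GRanges")) {
    return(tibble::tibble(chrom = as.character(GenomicRanges::seqnames(x)),
                          start = BiocGenerics::start(x) - 1L,
                          end = BiocGenerics::end(x)))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_bed(x))
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x
}

#' Read / write BED intervals
#'
#' Thin wrappers over plain tab-separated BED: intervals are kept 0-based
#' half-open, matching the package's internal convention.
#'
#' @param path File path.
#' @return For `read_bed`, a tibble with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  tibble::as_tibble(df)
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (+ optional columns).
#' @export
write_bed <- function(intervals, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[keep], path, col_names = FALSE)
  invisible(path)
}

#' Assign peaks to genome categories
#'
#' Each peak is assigned to the category with which it shares the most
#' bases; ties are broken promoter > gene body > intergenic. With
#' `method = "midpoint"` the category of the peak midpoint is used instead.
#'
#' @param peaks BED path, GRanges, or tibble with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param map A [category_map()].
#' @param method Assignment rule.
#' @return Tibble with `category`, `n_peaks`, `proportion` (percent; empty
#'   when there are no peaks).
#' @export
classify_peak_regions <- function(peaks, map,
                                  method = c("overlap", "midpoint")) {
  method <- match.arg(method)
  peaks <- as_intervals(peaks)
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(category = character(), n_peaks = integer(),
                          proportion = numeric()))
  }
  bad <- !peaks$chrom %in% names(map$genome_lengths)
  if (any(bad)) {
    stop("peak(s) on unknown chromosome(s): ",
         paste(unique(peaks$chrom[bad]), collapse = ", "))
  }
  pg <- if (method == "midpoint") {
    mid <- (peaks$start + peaks$end) %/% 2L
    GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  } else {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$start + 1L, peaks$end))
  }
  ov_bases <- function(cat_gr) {
    out <- numeric(length(pg))
    ov <- GenomicRanges::findOverlaps(pg, cat_gr, ignore.strand = TRUE)
    if (length(ov)) {
      w <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(pg)[S4Vectors::queryHits(ov)],
        IRanges::ranges(cat_gr)[S4Vectors::subjectHits(ov)]
      ))
      agg <- tapply(w, S4Vectors::queryHits(ov), sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  p <- ov_bases(map$promoter)
  g <- ov_bases(map$gene_body)
  i <- BiocGenerics::width(pg) - p - g
  cat <- c("promoter", "gene_body", "intergenic")[
    max.col(cbind(p, g, i), ties.method = "first")
  ]
  counts <- table(factor(cat, levels = c("promoter", "gene_body",
                                         "intergenic")))
  tibble::tibble(category = names(counts),
                 n_peaks = as.integer(counts),
                 proportion = 100 * as.integer(counts) / nrow(peaks))
}

#' Putative 3' UTR downstream of a CDS
#'
#' Strand-aware interval of `span` nt immediately downstream of each
#' candidate's CDS end, clipped at the contig edge.
#'
#' @param candidates Tibble with `chrom`, `strand`, and `orf_start`/`orf_end`
#'   (or `cds_start`/`cds_end`), 0-based half-open.
#' @param genome_lengths Named chromosome lengths.
#' @param span UTR span in nt.
#' @return `candidates` with added `utr_start`, `utr_end`, `utr_clipped`.
#' @export
putative_utr <- function(candidates, genome_lengths, span = 3000L) {
  cs <- candidates[[if ("orf_start" %in% names(candidates)) "orf_start"
                    else "cds_start"]]
  ce <- candidates[[if ("orf_end" %in% names(candidates)) "orf_end"
                    else "cds_end"]]
  L <- unname(genome_lengths[candidates$chrom])
  plus <- candidates$strand == "+"
  us <- ifelse(plus, ce, pmax(0L, cs - span))
  ue <- ifelse(plus, pmin(L, ce + span), cs)
  dplyr::mutate(candidates, utr_start = as.integer(us),
                utr_end = as.integer(ue),
                utr_clipped = (ue - us) < span)
}

#' Reads-per-million quantification over regions
#'
#' RPM(region) = overlapping reads x 1e6 / total mapped reads. A read counts
#' for a region when it overlaps by at least one base
#' (`mode = "five_prime"`: when its 5' end falls inside the region).
#'
#' @param reads BED path, GRanges, or tibble of read intervals (needs
#'   `strand` for `mode = "five_prime"`).
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param total_mapped_reads Total mapped reads for normalization (> 0).
#' @param mode Counting rule.
#' @return `regions` with added `n_reads` and `rpm`.
#' @export
rpm_quantify <- function(reads, regions, total_mapped_reads,
                         mode = c("overlap", "five_prime")) {
  mode <- match.arg(mode)
  if (!isTRUE(total_mapped_reads > 0)) {
    stop("total_mapped_reads must be > 0")
  }
  reads <- as_intervals(reads)
  if (mode == "five_prime") {
    if (!"strand" %in% names(reads)) {
      stop("mode = 'five_prime' needs a strand column on the reads")
    }
    p5 <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
    rg <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(p5 + 1L, p5 + 1L))
  } else {
    rg <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start + 1L, reads$end))
  }
  qg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  n <- GenomicRanges::countOverlaps(qg, rg, ignore.strand = TRUE)
  dplyr::mutate(regions, n_reads = as.integer(n),
                rpm = n * 1e6 / total_mapped_reads)
}
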