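#' Run the full in silico hybridization screen
#'
#' Chains the whole pipeline: peptide windows -> degenerate genome scan ->
#' locus merge -> ORF reconstruction -> length and core-domain filters ->
#' optional annotation labels, and records the count at every stage (the
#' screen's reproducibility surface).
#'
#' @param query A [protein_query()] (default: the histone H3.2 query).
#' @param genome Genome as in [scan_genome()].
#' @param k Window length (aa).
#' @param max_gap Locus merge gap (nt).
#' @param min_distinct Minimum distinct window peptides per locus.
#' @param min_peptide_len Minimum predicted peptide length (aa).
#' @param annotations Optional gene-model tibble ([read_gene_models()]).
#' @param require_atg Passed to [reconstruct_orfs()].
#' @return A `hyb_screen` object: list with `query`, `params`, `windows`,
#'   `hits`, `loci` (filter-annotated), and `summary` (stage counts).
#' @export
run_screen <- function(query = h3_query(), genome, k = 8L, max_gap = 90L,
                       min_distinct = 2L, min_peptide_len = 10L,
                       annotations = NULL, require_atg = FALSE) {
  genome <- as_genome(genome)
  windows <- make_windows(query, k = k)
  n_seq <- count_reverse_translations(windows)
  hits <- scan_genome(genome, windows)
  loci <- merge_hits(hits, max_gap = max_gap, min_distinct = min_distinct) |>
    reconstruct_orfs(genome, query, require_atg = require_atg) |>
    apply_filters(min_peptide_len = min_peptide_len)
  if (!is.null(annotations)) loci <- label_candidates(loci, annotations)
  summary <- tibble::tibble(
    stage = c("windows", "enumerable_sequences", "hits", "loci",
              "after_length_filter", "after_core_filter"),
    count = c(nrow(windows), n_seq, nrow(hits), nrow(loci),
              sum(!loci$too_short), sum(loci$pass))
  )
  structure(list(
    query = query,
    params = list(k = k, max_gap = max_gap, min_distinct = min_distinct,
                  min_peptide_len = min_peptide_len,
                  core_range = query$core_range, require_atg = require_atg),
    windows = windows, hits = hits, loci = loci, summary = summary
  ), class = "hyb_screen")
}

#' @export
print.hyb_screen <- function(x, ...) {
  cat("<hyb_screen> query ", x$query$id, " (", nchar(x$query$sequence),
      " aa), k = ", x$params$k, "\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-22s %s\n", x$summary$stage[i],
                format(x$summary$count[i], big.mark = ",")))
  }
  invisible(x)
}

#' @method tidy hyb_screen
#' @export
tidy.hyb_screen <- function(x, ...) {
  dplyr::select(x$loci, -dplyr::any_of("hits"))
}

#' @method glance hyb_screen
#' @export
glance.hyb_screen <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$summary$count,
                                                   x$summary$stage)))
  dplyr::mutate(out, k = x$params$k, max_gap = x$params$max_gap,
                min_distinct = x$params$min_distinct,
                min_peptide_len = x$params$min_peptide_len)
}

#' Write all screen reports
#'
#' Writes hits BED, candidate GFF3 and TSV, the stage-count summary, and a
#' JSON run manifest (parameters plus input checksums) into `dir`.
#'
#' @param screen A [run_screen()] result.
#' @param dir Output directory.
#' @param inputs Optional named character vector of input file paths to
#'   checksum into the manifest.
#' @return `dir`, invisibly.
#' @export
write_screen_reports <- function(screen, dir, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hits_bed(screen$hits, file.path(dir, "hits.bed"))
  write_candidates_gff3(screen$loci, file.path(dir, "candidates.gff3"))
  write_candidates_tsv(screen$loci, file.path(dir, "candidates.tsv"))
  readr::write_tsv(screen$summary, file.path(dir, "summary.tsv"))
  manifest <- c(screen$params,
                list(query_id = screen$query$id,
                     query_length = nchar(screen$query$sequence),
                     inputs = as.list(tools::md5sum(inputs))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
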