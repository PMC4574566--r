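write_toy_refflat <- function(path) {
  lines <- c(
    paste("H3f3a", "tx1", "chr1", "+", 1000, 3000, 1200, 2800, 2,
          "1000,2000,", "1500,3000,", sep = "\t"),
    paste("Gm12260", "tx2", "chr1", "-", 5000, 6000, 5000, 6000, 1,
          "5000,", "6000,", sep = "\t"),
    paste("Hist1h3a-ps1", "tx3", "chr2", "+", 100, 700, 100, 700, 1,
          "100,", "700,", sep = "\t")
  )
  writeLines(lines, path)
  path
}

write_toy_gtf <- function(path) {
  gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
    paste(chrom, "toy", type, start, end, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                  gene, tx, gene), sep = "\t")
  }
  writeLines(c(
    gtf_line("chr1", "exon", 1001, 1500, "+", "H3f3a", "tx1"),
    gtf_line("chr1", "exon", 2001, 3000, "+", "H3f3a", "tx1"),
    gtf_line("chr1", "CDS", 1201, 1500, "+", "H3f3a", "tx1"),
    gtf_line("chr1", "CDS", 2001, 2800, "+", "H3f3a", "tx1"),
    gtf_line("chr1", "exon", 5001, 6000, "-", "Gm12260", "tx2"),
    gtf_line("chr2", "exon", 101, 700, "+", "Hist1h3a-ps1", "tx3")
  ), path)
  path
}

test_that("refFlat and GTF encodings of the same genes import identically", {
  rf <- read_gene_models(write_toy_refflat(withr::local_tempfile()),
                         format = "refflat")
  gt <- read_gene_models(write_toy_gtf(withr::local_tempfile(fileext = ".gtf")))
  expect_equal(nrow(rf), 3L)
  cols <- c("gene", "transcript", "chrom", "strand", "tx_start", "tx_end")
  expect_equal(as.data.frame(dplyr::arrange(rf[cols], transcript)),
               as.data.frame(dplyr::arrange(gt[cols], transcript)))
  expect_equal(rf$exon_starts[[1]], c(1000L, 2000L))
  expect_equal(gt$exon_starts[[1]], c(1000L, 2000L))
  expect_equal(rf$exon_ends[[1]], c(1500L, 3000L))
})

test_that("malformed refFlat lines are rejected with their line number", {
  bad <- withr::local_tempfile()
  writeLines(paste("g", "t", "chr1", "+", 0, 100, 0, 100, 2,
                   "0,", "100,", sep = "\t"), bad)
  expect_error(read_gene_models(bad, format = "refflat"), "line 1")
  short <- withr::local_tempfile()
  writeLines("gene\ttx\tchr1", short)
  expect_error(read_gene_models(short, format = "refflat"), "11")
})

test_that("candidate labels follow known > pseudogene > predicted > unannotated", {
  models <- read_gene_models(write_toy_refflat(withr::local_tempfile()),
                             format = "refflat")
  loci <- tibble::tibble(
    locus_id = paste0("l", 1:4),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1100L, 5500L, 200L, 5000L),
    end = c(1300L, 5600L, 400L, 5200L)
  )
  lab <- label_candidates(loci, models)
  expect_equal(lab$annotation,
               c("known", "predicted", "pseudogene", "unannotated"))
  # stable under input reordering
  lab_rev <- label_candidates(loci[4:1, ], models)
  expect_equal(lab_rev$annotation, rev(lab$annotation))
  # precedence: a locus overlapping both a known and a predicted model
  both <- dplyr::bind_rows(models, dplyr::mutate(models[2, ], gene = "Actb",
                                                 transcript = "tx9"))
  expect_equal(label_candidates(loci[2, ], both)$annotation, "known")
})

test_that("genome category fractions partition the genome and sum to 100", {
  # one 1,000-nt gene centred on a 100-kb chromosome
  models <- tibble::tibble(gene = "g", transcript = "t", chrom = "chr1",
                           strand = "+", tx_start = 49500L, tx_end = 50500L,
                           cds_start = 49500L, cds_end = 50500L,
                           exon_starts = list(49500L), exon_ends = list(50500L))
  fr <- genome_category_fractions(models, c(chr1 = 100000L))
  expect_equal(fr$fraction[fr$category == "promoter"], 4.0)
  expect_equal(sum(fr$fraction), 100, tolerance = 1e-12)
  # promoter carve-out: gene body excludes promoter bases
  expect_equal(fr$bases[fr$category == "gene_body"],
               1000 - sum(49500:50499 >= 47500 & 49500:50499 < 51500))
  # zero genes: all intergenic
  fr0 <- genome_category_fractions(models[0, ], c(chr1 = 5000L))
  expect_equal(fr0$fraction, c(0, 0, 100))
  # random model sets always sum to 100
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(1:10, 1)
    st <- sort(sample(0:80000, n))
    mm <- tibble::tibble(gene = paste0("g", 1:n), transcript = paste0("t", 1:n),
                         chrom = "chr1", strand = sample(c("+", "-"), n, TRUE),
                         tx_start = st, tx_end = st + sample(500:8000, n, TRUE),
                         cds_start = st, cds_end = st,
                         exon_starts = as.list(st), exon_ends = as.list(st + 1L))
    fr <- suppressWarnings(genome_category_fractions(mm, c(chr1 = 100000L)))
    expect_equal(sum(fr$fraction), 100, tolerance = 1e-9)
    expect_true(all(fr$bases >= 0))
  }
})

test_that("peak assignment uses maximal overlap with promoter-first ties", {
  models <- tibble::tibble(gene = "g", transcript = "t", chrom = "chr1",
                           strand = "+", tx_start = 10000L, tx_end = 20000L,
                           cds_start = 10000L, cds_end = 20000L,
                           exon_starts = list(10000L), exon_ends = list(20000L))
  cm <- category_map(models, c(chr1 = 50000L), promoter_halfwidth = 2000L)
  # promoter occupies [8000, 12000); gene body [12000, 20000)
  wholly_intergenic <- tibble::tibble(chrom = "chr1", start = 30000L,
                                      end = 30500L)
  expect_equal(classify_peak_regions(wholly_intergenic, cm) |>
                 dplyr::filter(n_peaks > 0) |> dplyr::pull(category),
               "intergenic")
  straddle <- tibble::tibble(chrom = "chr1", start = 11800L, end = 12200L)
  expect_equal(classify_peak_regions(straddle, cm) |>
                 dplyr::filter(n_peaks > 0) |> dplyr::pull(category),
               "promoter")
  mix <- tibble::tibble(
    chrom = "chr1",
    start = c(8100L, 8200L, rep(13000L, 5), rep(30000L, 3)),
    end = c(8150L, 8250L, rep(13100L, 5), rep(30100L, 3))
  )
  props <- classify_peak_regions(mix, cm)
  expect_equal(props$proportion, c(20, 50, 30))
  expect_equal(sum(props$proportion), 100, tolerance = 1e-9)
  expect_equal(nrow(classify_peak_regions(mix[0, ], cm)), 0L)
})

test_that("putative UTRs are strand-aware 3-kb downstream intervals, clipped at edges", {
  cand <- tibble::tibble(chrom = "chr1", strand = c("+", "-", "+"),
                         orf_start = c(2000L, 5000L, 6500L),
                         orf_end = c(5000L, 8000L, 7000L))
  utr <- putative_utr(cand, c(chr1 = 8000L))
  expect_equal(utr$utr_start, c(5000L, 2000L, 7000L))
  expect_equal(utr$utr_end, c(8000L, 5000L, 8000L))
  expect_equal(utr$utr_clipped, c(FALSE, FALSE, TRUE))
  expect_true(all(utr$utr_end - utr$utr_start <= 3000L))
})

test_that("RPM is linear, scale-invariant, and guards the zero-total case", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  reads <- tibble::tibble(chrom = "chr1", start = seq(0L, 900L, by = 100L),
                          end = seq(50L, 950L, by = 100L))
  r <- rpm_quantify(reads, regions, total_mapped_reads = 1e6)
  expect_equal(r$rpm, 10)
  expect_equal(rpm_quantify(reads[0, ], regions, 1e6)$rpm, 0)
  # doubling counts and total leaves RPM unchanged
  r2 <- rpm_quantify(dplyr::bind_rows(reads, reads), regions, 2e6)
  expect_equal(r2$rpm, r$rpm)
  expect_error(rpm_quantify(reads, regions, 0), "total_mapped_reads")
})
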