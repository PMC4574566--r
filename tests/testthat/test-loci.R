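test_that("locus merging respects the 90-nt gap boundary and distinct-window rule", {
  a <- hit_row(0, "AAAAAAAA", window_index = 0)
  b_at <- function(s) hit_row(s, "CCCCCCCC", window_index = 5)
  # gap exactly 90 nt joins; 91 nt leaves two singletons, both discarded
  expect_equal(nrow(merge_hits(dplyr::bind_rows(a, b_at(114)))), 1L)
  expect_equal(nrow(merge_hits(dplyr::bind_rows(a, b_at(115)))), 0L)
  # one isolated hit is never a locus
  expect_equal(nrow(merge_hits(a)), 0L)
  # two hits of the same window peptide do not reach min_distinct = 2
  same <- dplyr::bind_rows(hit_row(0, "AAAAAAAA"), hit_row(50, "AAAAAAAA"))
  expect_equal(nrow(merge_hits(same)), 0L)
  expect_equal(nrow(merge_hits(same, min_distinct = 1)), 1L)
  # transitive chaining: neighbours within 90 nt, ends > 90 nt apart
  chain <- dplyr::bind_rows(a, b_at(100), hit_row(200, "GGGGGGGG"))
  m <- merge_hits(chain)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 224L))
  # hits on different strands or chromosomes never merge
  split2 <- dplyr::bind_rows(a, hit_row(30, "CCCCCCCC", strand = "-"))
  expect_equal(nrow(merge_hits(split2)), 0L)
})

test_that("emitted loci are maximal on fuzzed hit sets", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    hits <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(0:3000, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      window_index = sample(0:20, n, replace = TRUE)
    ) |>
      dplyr::mutate(end = start + 24L,
                    peptide = paste0("P", window_index)) |>
      dplyr::select(chrom, start, end, strand, window_index, peptide)
    loci <- merge_hits(hits)
    expect_true(all(loci$n_distinct_windows >= 2))
    gaps <- loci |>
      dplyr::group_by(chrom, strand) |>
      dplyr::arrange(start, .by_group = TRUE) |>
      dplyr::summarise(min_gap = if (dplyr::n() < 2) Inf else
        min(dplyr::lead(start) - end, na.rm = TRUE), .groups = "drop")
    expect_true(all(gaps$min_gap > 90))
  }
})

test_that("ORF reconstruction recovers implanted proteins exactly, both strands", {
  q <- h3_query()
  sim <- simulate_genome(
    implant_spec(kind = c("exact_cds", "exact_cds"), strand = c("+", "-")),
    seed = 61, query = q, chrom_lengths = c(chrA = 6000L)
  )
  sc <- run_screen(q, sim$genome)
  loci <- dplyr::arrange(sc$loci, start)
  truth <- dplyr::arrange(sim$truth, cds_start)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$protein, rep(q$sequence, 2))
  expect_equal(loci$orf_start, truth$cds_start)
  expect_equal(loci$orf_end, truth$cds_end)
  expect_equal(loci$strand, truth$strand)
  expect_true(all(loci$pass))
})

test_that("a frameshift upstream of the core domain flags CORE_OUT_OF_FRAME", {
  q <- h3_query()
  sim <- simulate_genome(
    implant_spec(kind = "frameshift_pseudogene", fs_codon = 30L, indel = -1L),
    seed = 62, query = q, chrom_lengths = c(chrA = 4000L)
  )
  sc <- run_screen(q, sim$genome)
  expect_equal(nrow(sc$loci), 1L)
  expect_false(sc$loci$core_covered_in_frame)
  expect_match(sc$loci$filter_flags, "CORE_OUT_OF_FRAME")
})

test_that("a frameshift downstream of the core domain can still pass", {
  q <- h3_query(core_range = c(63L, 100L))
  sim <- simulate_genome(
    implant_spec(kind = "frameshift_pseudogene", fs_codon = 120L, indel = -1L),
    seed = 63, query = q, chrom_lengths = c(chrA = 4000L)
  )
  sc <- run_screen(q, sim$genome)
  expect_equal(nrow(sc$loci), 1L)
  expect_true(sc$loci$core_covered_in_frame)
  expect_equal(sc$loci$filter_flags, "PASS")
})

test_that("short encoded peptides are rejected as TOO_SHORT at the 10-aa boundary", {
  q <- h3_query()
  sim <- simulate_genome(
    implant_spec(kind = c("truncated_fragment", "truncated_fragment"),
                 frag_start = c(2L, 2L), frag_len = c(9L, 12L)),
    seed = 64, query = q, chrom_lengths = c(chrA = 5000L)
  )
  sc <- run_screen(q, sim$genome)
  loci <- dplyr::arrange(sc$loci, start)
  expect_equal(loci$protein_length, c(9L, 12L))
  expect_true(loci$too_short[1])
  expect_false(loci$too_short[2])
  expect_match(loci$filter_flags[1], "TOO_SHORT")
})

test_that("recoded implants give identical locus spans and proteins as their twins", {
  set.seed(65)
  q <- h3_query()
  w <- make_windows(q)
  cds <- protein_to_cds(q$sequence)
  bg1 <- random_dna_str(400)
  bg2 <- random_dna_str(1000)
  build <- function(c_) c(chr1 = paste0(bg1, "TAA", c_, "TAA", bg2))
  base <- run_screen(q, build(cds))
  for (rate in c(0.25, 0.75, 1)) {
    twin <- run_screen(q, build(recode_synonymous(cds, rate)))
    expect_equal(twin$loci[c("chrom", "strand", "start", "end")],
                 base$loci[c("chrom", "strand", "start", "end")])
    expect_equal(twin$loci$protein, base$loci$protein)
  }
})

test_that("tightening merge or length parameters never increases passing loci", {
  sim <- simulate_genome(demo_implants(), seed = 66)
  q <- h3_query()
  base <- run_screen(q, sim$genome)
  tighter_gap <- run_screen(q, sim$genome, max_gap = 30L)
  longer_min <- run_screen(q, sim$genome, min_peptide_len = 50L)
  more_distinct <- run_screen(q, sim$genome, min_distinct = 5L)
  expect_lte(sum(tighter_gap$loci$pass), sum(base$loci$pass))
  expect_lte(sum(longer_min$loci$pass), sum(base$loci$pass))
  expect_lte(nrow(more_distinct$loci), nrow(base$loci))
})
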