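test_that("edit distance satisfies metric properties and matches the recursion oracle", {
  expect_equal(levenshtein("KITTEN", "KITTEN"), 0L)
  expect_equal(levenshtein("AAAA", "AAAT"), 1L)
  set.seed(81)
  for (rep in 1:40) {
    a <- random_protein(sample(0:8, 1))
    b <- random_protein(sample(0:8, 1))
    d <- levenshtein(a, b)
    expect_equal(d, lev_oracle(a, b))
    expect_equal(d, levenshtein(b, a))
    expect_gte(d, abs(nchar(a) - nchar(b)))
    cc <- random_protein(sample(0:8, 1))
    expect_lte(levenshtein(a, cc), d + levenshtein(b, cc))
  }
  # cross-check against the generalized distance in base R on longer pairs
  for (rep in 1:10) {
    a <- random_protein(40)
    b <- random_protein(35)
    expect_equal(levenshtein(a, b),
                 as.integer(utils::adist(a, b)))
  }
})

test_that("percent identity uses the longer length as denominator", {
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
  ref <- h3_reference_proteins()
  expect_equal(percent_identity(ref[["H3.3"]], ref[["H3.3"]]), 100)
  expect_error(percent_identity("", ""), "empty")
  # near variants of H3.3 stay in the reported identity band
  set.seed(82)
  for (n in c(2, 11, 23)) {
    v <- spaced_variant(ref[["H3.3"]], n)
    expect_gte(percent_identity(v, ref[["H3.3"]]), 76)
  }
})

test_that("substitution notation reproduces the H3 diagnostic substitutions", {
  ref <- h3_reference_proteins()
  expect_equal(substitution_notation(ref[["H3.3"]], ref[["H3.2"]]),
               "A31S, S87A, V89I, M90G")
  expect_equal(substitution_notation(ref[["H3.2"]], ref[["H3.1"]]), "C96S")
  expect_equal(substitution_notation(ref[["H3.3"]], ref[["H3.3"]]), "")
  # the Met-inclusive encoding with numbering_offset = 1 gives mature positions
  expect_equal(
    substitution_notation(paste0("M", ref[["H3.3"]]),
                          paste0("M", ref[["H3.2"]]), numbering_offset = 1L),
    "A31S, S87A, V89I, M90G"
  )
  # an H3mm7-style variant built from its notation round-trips
  mm7 <- apply_substitution_notation(ref[["H3.3"]], "T32I, S57A")
  expect_equal(substitution_notation(mm7, ref[["H3.3"]]), "T32I, S57A")
  # length-divergent or heavily substituted pairs collapse to #distance
  expect_equal(substitution_notation("ARTK", "ARTKQTAR"), "#4")
  set.seed(83)
  far <- spaced_variant(ref[["H3.3"]], 12)
  expect_match(substitution_notation(far, ref[["H3.3"]]), "^#")
  # round trip on random equal-length pairs
  for (rep in 1:10) {
    base <- random_protein(60)
    v <- spaced_variant(base, sample(1:5, 1), gap = 8L)
    expect_equal(
      apply_substitution_notation(base, substitution_notation(v, base)), v
    )
  }
})

test_that("the 87-90 motif separates H3.1-type from H3.3-type sequences", {
  ref <- h3_reference_proteins()
  expect_equal(motif_87_90(ref[["H3.1"]]), "SAVM")
  expect_equal(motif_87_90(ref[["H3.2"]]), "SAVM")
  expect_equal(motif_87_90(ref[["H3.3"]]), "AAIG")
  # H3mm10- and H3mm17-style variants: AVIG and SAIG
  expect_equal(motif_87_90(apply_substitution_notation(ref[["H3.3"]], "A88V")),
               "AVIG")
  expect_equal(motif_87_90(apply_substitution_notation(ref[["H3.3"]], "A87S")),
               "SAIG")
  expect_equal(motif_87_90(paste0("M", ref[["H3.1"]]), numbering_offset = 1L),
               "SAVM")
  expect_true(is.na(motif_87_90("ARTKQTAR")))
})

test_that("hierarchical grouping places variants with the expected reference clades", {
  set.seed(84)
  ref <- h3_reference_proteins()
  cands <- c(
    near_h33 = spaced_variant(ref[["H3.3"]], 2),
    h3t_like = spaced_variant(ref[["H3.1"]], 3),
    distA = spaced_variant(ref[["H3.3"]], 15),
    distB = spaced_variant(ref[["H3.3"]], 40)
  )
  g <- cluster_variants(cands)
  got <- setNames(g$groups$group, g$groups$name)
  expect_equal(unname(got["near_h33"]), "H3.3-group")
  expect_equal(unname(got["h3t_like"]), "H3.1-group")
  expect_equal(unname(got["distA"]), "distant-A")
  expect_equal(unname(got["distB"]), "distant-B")
  expect_equal(unname(got[c("H3.1", "H3.2")]), rep("H3.1-group", 2))
  # invariant under input order and duplicated sequences
  g2 <- cluster_variants(rev(cands))
  expect_equal(dplyr::arrange(tidy(g2), name), dplyr::arrange(tidy(g), name))
  g3 <- cluster_variants(c(cands, near_h33_dup = unname(cands["near_h33"])))
  got3 <- setNames(g3$groups$group, g3$groups$name)
  expect_equal(unname(got3[names(got)]), unname(got))
  expect_error(cluster_variants(character(0), references = ref["H3.1"]),
               "H3.3")
  # newick export round-trips through ape
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(g, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, g$groups$name)
})

test_that("3'-end classification prefers stem-loop over poly-A and is strand-aware", {
  sl <- hybscreen:::.CANONICAL_STEM_LOOP
  clean <- strrep("ACG", 120) # no AATAAA/ATTAAA, no T for a loop
  expect_equal(classify_downstream_seq(clean)$three_prime_class, "NotDetected")
  with_pa <- paste0(substr(clean, 1, 50), "AATAAA", substr(clean, 57, 360))
  expect_equal(classify_downstream_seq(with_pa)$three_prime_class, "PolyA")
  with_both <- paste0(substr(clean, 1, 30), "AATAAA", strrep("C", 20), sl,
                      substr(clean, 80, 360))
  both <- classify_downstream_seq(with_both)
  expect_equal(both$three_prime_class, "StemLoop")
  expect_equal(both$motif, sl)
  # genomic interface: motif downstream of a minus-strand CDS
  genome <- c(chr1 = paste0(strrep("ACG", 40),
                            hybscreen:::revcomp_chr(paste0(strrep("GCA", 10), sl)),
                            strrep("ACG", 40)))
  res <- classify_three_prime_end(genome, "chr1", cds_end = 166L,
                                  strand = "-", search_span = 100L)
  expect_equal(res$three_prime_class, "StemLoop")
  # deterministic: repeated calls agree
  expect_identical(classify_downstream_seq(with_both),
                   classify_downstream_seq(with_both))
})

test_that("the report table picks closest references and carries simulator truth", {
  set.seed(85)
  ref <- h3_reference_proteins()
  sim <- simulate_genome(
    implant_spec(kind = c("exact_cds", "substituted_variant"),
                 n_subs = c(NA, 2L), three_prime = c("stemloop", "polyA")),
    seed = 86, chrom_lengths = c(chrA = 6000L)
  )
  sc <- run_screen(h3_query(), sim$genome)
  cands <- sc$loci |>
    dplyr::mutate(name = locus_id,
                  protein = substr(protein, 2L, nchar(protein))) |> # mature
    dplyr::select(name, protein, chrom, strand, orf_start, orf_end)
  rep_tbl <- build_report_table(cands, genome = sim$genome)
  expect_equal(nrow(rep_tbl), 2L)
  truth <- dplyr::arrange(sim$truth, cds_start)
  got <- rep_tbl[match(dplyr::arrange(sc$loci, start)$locus_id, rep_tbl$name), ]
  # re-discovered exact query: distance 0, empty notation, H3.1-group motif
  exact_row <- got[truth$kind == "exact_cds", ]
  expect_equal(exact_row$aa_edit_distance, 0L)
  expect_equal(exact_row$substitutions, "")
  expect_equal(exact_row$closest_reference, "H3.2")
  expect_equal(exact_row$motif_87_90, "SAVM")
  expect_equal(exact_row$three_prime_class, "StemLoop")
  sub_row <- got[truth$kind == "substituted_variant", ]
  expect_equal(sub_row$aa_edit_distance, 2L)
  expect_equal(length(strsplit(sub_row$substitutions, ",")[[1]]), 2L)
  expect_equal(sub_row$three_prime_class, "PolyA")
  # ties between references break in reference order
  tie <- build_report_table(tibble::tibble(name = "mid",
                                           protein = ref[["H3.2"]]),
                            references = ref[c("H3.1", "H3.2", "H3.3")])
  expect_equal(tie$closest_reference, "H3.2")
  # empty candidate set: empty report with the full header
  empty <- build_report_table(tibble::tibble(name = character(),
                                             protein = character()))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("closest_reference", "group", "three_prime_class") %in%
                    names(empty)))
})
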